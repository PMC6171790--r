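# Fixture export and standard-format ingestion. Genotypes travel as PED/MAP
# and VCF 4.2 (phased GT), intensities and phenotypes as TSV, alignments as
# SAM 1.6 text, the true duplication as BED3, and the full simulation truth
# as a JSON manifest for test oracles.

#' Write a synthetic cohort (and companions) to standard file formats
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param intensities Optional log R matrix from [simulate_intensities()].
#' @param alignments Optional alignment tibble from
#'   [simulate_read_alignments()].
#' @param read_config Optional [read_sim_config()] used for `alignments`;
#'   required to write a correct SAM header and the truth BED for reads.
#' @return A tibble manifest of the files written (`file`, `path`,
#'   `n_records`), invisibly usable as a round-trip index.
#' @export
write_fixtures <- function(cohort, out_dir, intensities = NULL,
                           alignments = NULL, read_config = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_bad_arg("cannot create output directory '%s'", out_dir)
  paths <- character()
  counts <- integer()
  add <- function(file, n) {
    paths[[file]] <<- file.path(out_dir, file)
    counts[[file]] <<- as.integer(n)
    paths[[file]]
  }
  n <- nrow(cohort$dogs); m <- nrow(cohort$markers)
  hap <- cohort$haplotypes

  # PED/MAP: alleles A (ref, code 0) and B (alt, code 1); phenotype 1/2
  allele <- function(x) c("A", "B")[x + 1L]
  ped_geno <- vapply(seq_len(m), function(j)
    paste(allele(hap[, 1L, j]), allele(hap[, 2L, j])), character(n))
  ped <- data.frame(fid = cohort$dogs$breed_label, iid = cohort$dogs$dog_id,
                    pat = 0L, mat = 0L, sex = 0L,
                    pheno = cohort$dogs$phenotype + 1L, ped_geno)
  utils::write.table(ped, add("genotypes.ped", n), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  map <- data.frame(chrom = 18L, id = cohort$markers$marker_id, cm = 0,
                    pos = cohort$markers$pos)
  utils::write.table(map, add("genotypes.map", m), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  # VCF 4.2, phased GT
  gt <- vapply(seq_len(n), function(i)
    paste0(hap[i, 1L, ], "|", hap[i, 2L, ]), character(m))
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=18,length=%d>", cohort$config$region_end + 1L),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$dogs$dog_id), collapse = "\t"),
    paste(18L, cohort$markers$pos, cohort$markers$marker_id, "A", "C", ".",
          "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(vcf_lines, add("genotypes.vcf", m))

  readr::write_tsv(
    dplyr::select(cohort$dogs, "dog_id", "phenotype"),
    add("phenotypes.tsv", n), progress = FALSE)

  if (!is.null(intensities)) {
    df <- tibble::as_tibble(intensities, rownames = "dog_id")
    readr::write_tsv(df, add("intensities.tsv", n), progress = FALSE)
  }
  if (!is.null(alignments)) {
    ref_len <- if (!is.null(read_config)) read_config$reference_length
      else max(alignments$end)
    write_sam(alignments, add("alignments.sam", nrow(alignments)),
              reference_length = ref_len)
  }

  # truth BED is 0-based half-open; internal coordinates 1-based inclusive
  dup <- if (!is.null(read_config))
    c("chrS", read_config$dup_start, read_config$dup_end)
    else c("18", cohort$dup_start, cohort$dup_end)
  writeLines(sprintf("%s\t%d\t%d", dup[1], as.integer(dup[2]) - 1L,
                     as.integer(dup[3])), add("truth_dup.bed", 1L))

  truth <- list(
    dup_start = cohort$dup_start, dup_end = cohort$dup_end,
    read_dup_start = if (!is.null(read_config)) read_config$dup_start,
    read_dup_end = if (!is.null(read_config)) read_config$dup_end,
    dup_copies = setNames(as.list(cohort$dogs$dup_copies),
                          cohort$dogs$dog_id),
    core_markers = names(cohort$core_alleles),
    core_positions = cohort$markers$pos[match(names(cohort$core_alleles),
                                              cohort$markers$marker_id)],
    core_alleles = unname(cohort$core_alleles),
    in_dup_markers = cohort$markers$marker_id[cohort$markers$in_dup],
    partial_dog = cohort$partial_dog,
    seed = cohort$config$seed)
  jsonlite::write_json(truth, add("truth.json", 1L), auto_unbox = TRUE,
                       null = "null", digits = NA)

  tibble::tibble(file = names(paths), path = unname(paths),
                 n_records = unname(counts))
}

#' Write alignments as SAM text
#'
#' @param alignments Alignment tibble (see [simulate_read_alignments()]).
#' @param path Output `.sam` path.
#' @param reference_length Contig length for the `@SQ` header line.
#' @param rname Contig name.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference_length,
                      rname = alignments$rname[1] %||% "chrS") {
  a <- alignments
  seq_str <- strrep("N", a$read_len %||% 100L)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", rname, as.integer(reference_length)),
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
            a$qname, a$flag, rname, a$pos, a$cigar, a$mpos, a$tlen, seq_str))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SAM/BAM file into the alignment tibble used by the detectors
#'
#' SAM text is converted with `Rsamtools::asBam()` and scanned; mate strand
#' is decoded from the flag bits.
#'
#' @param path A `.sam` or `.bam` file.
#' @return Alignment tibble with `qname`, `flag`, `rname`, `pos`, `end`,
#'   `strand`, `cigar`, `mpos`, `mate_strand`, `tlen`, `read_len`.
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mpos",
               "isize", "cigar")))[[1]]
  qw <- ifelse(is.na(res$qwidth), 100L, res$qwidth)
  tibble::tibble(
    qname = res$qname, flag = res$flag, rname = as.character(res$rname),
    pos = res$pos, end = res$pos + qw - 1L,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
    cigar = res$cigar, mpos = res$mpos,
    mate_strand = ifelse(bitwAnd(res$flag, 32L) > 0L, "-", "+"),
    tlen = res$isize, read_len = qw)
}

#' Read genotypes (and phase) from a VCF file
#'
#' @param path VCF path (plain text or gzipped), GT format field required.
#' @return A list with `genotypes` (samples x markers alt-allele dosage
#'   matrix), `haplotypes` (samples x 2 x markers array, `NA`-filled where
#'   unphased), `markers` (tibble: `marker_id`, `chrom`, `pos`) and `phased`
#'   (logical, all-sites phased).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  mids <- rownames(gt) %||% paste0("snp", seq_len(nrow(gt)))
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  sep <- substr(gt, 2L, 2L)
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  m <- nrow(gt); n <- ncol(gt)
  hap <- array(NA_integer_, c(n, 2L, m),
               dimnames = list(ids, c("h1", "h2"), mids))
  phased <- matrix(sep == "|", m, n)
  h1 <- matrix(a1, m, n); h2 <- matrix(a2, m, n)
  hap[, 1L, ] <- t(h1); hap[, 2L, ] <- t(h2)
  hap[, 1L, ][!t(phased)] <- NA_integer_
  hap[, 2L, ][!t(phased)] <- NA_integer_
  geno <- t(h1 + h2)
  dimnames(geno) <- list(ids, mids)
  list(genotypes = geno, haplotypes = hap,
       markers = tibble::tibble(marker_id = mids,
                                chrom = vcfR::getCHROM(v),
                                pos = vcfR::getPOS(v)),
       phased = all(phased, na.rm = TRUE))
}

#' Read genotypes from 6-column PED + 4-column MAP text files
#'
#' Alleles are re-coded against the first-seen allele per marker being "A"
#' (dosage counts "B" alleles); `0` is missing.
#'
#' @param ped,map File paths.
#' @return A list with `genotypes` (samples x markers dosage, `NA` missing),
#'   `phenotype` (0/1, from the PED phenotype column), and `markers`.
#' @export
read_plink_text <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE,
                          col.names = c("chrom", "marker_id", "cm", "pos"))
  pd <- utils::read.table(ped, header = FALSE, colClasses = "character")
  m <- nrow(mp)
  if (ncol(pd) != 6L + 2L * m)
    stop_bad_arg("PED has %d columns; expected %d for %d markers",
                 ncol(pd), 6L + 2L * m, m)
  n <- nrow(pd)
  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(pd[[2]], mp$marker_id))
  for (j in seq_len(m)) {
    x1 <- pd[[5L + 2L * j]]; x2 <- pd[[6L + 2L * j]]
    miss <- x1 == "0" | x2 == "0"
    geno[, j] <- (x1 == "B") + (x2 == "B")
    geno[miss, j] <- NA_integer_
  }
  list(genotypes = geno,
       phenotype = as.integer(pd[[6]]) - 1L,
       markers = tibble::as_tibble(mp))
}
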