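# Hard-filter variant triage: GATK-style per-annotation thresholds applied
# as strict rejection rules, carrier-exclusive variant identification, and a
# minimal consequence classification against a gene model.

#' Hard-filter thresholds for SNPs and indels
#'
#' Defaults mirror standard short-variant hard filters: reject on read depth
#' < 2 (both types), strand-bias Fisher phred FS > 60 (SNPs) / > 200
#' (indels), read-position rank-sum < -8 (SNPs) / < -20 (indels), and for
#' SNPs RMS mapping quality < 40 and mapping-quality rank-sum < -12.5.
#'
#' @param min_depth Minimum read depth (strict `<` rejects).
#' @param max_fs_snp,max_fs_indel Maximum phred-scaled strand-bias FS.
#' @param min_readpos_z_snp,min_readpos_z_indel Minimum read-position
#'   rank-sum z.
#' @param min_mq_rms_snp Minimum RMS mapping quality (SNPs only).
#' @param min_mqrank_z_snp Minimum mapping-quality rank-sum z (SNPs only).
#' @return A list of class `variant_filter_config`.
#' @export
variant_filter_config <- function(min_depth = 2,
                                  max_fs_snp = 60, max_fs_indel = 200,
                                  min_readpos_z_snp = -8,
                                  min_readpos_z_indel = -20,
                                  min_mq_rms_snp = 40,
                                  min_mqrank_z_snp = -12.5) {
  vals <- list(min_depth = min_depth, max_fs_snp = max_fs_snp,
               max_fs_indel = max_fs_indel,
               min_readpos_z_snp = min_readpos_z_snp,
               min_readpos_z_indel = min_readpos_z_indel,
               min_mq_rms_snp = min_mq_rms_snp,
               min_mqrank_z_snp = min_mqrank_z_snp)
  if (!all(vapply(vals, function(x) is.numeric(x) && is.finite(x),
                  logical(1))))
    stop_bad_arg("all filter thresholds must be finite numbers")
  structure(vals, class = "variant_filter_config")
}

variant_type <- function(ref, alt) {
  ifelse(nchar(ref) != nchar(alt), "indel", "SNP")
}

#' Apply hard filters to a variant table
#'
#' A variant is rejected when ANY applicable rule fires (strict
#' inequalities, e.g. a SNP with FS exactly 60 is retained, 60.1 rejected).
#' SNPs and indels are filtered in separate passes and merged. A missing
#' annotation means the rule is not applied to that variant; such skips are
#' counted.
#'
#' @param variants Tibble with `ref`, `alt` (or a `type` column in
#'   `c("SNP","indel")`) and annotation columns `depth`, `fs`, `readpos_z`,
#'   and for SNPs `mq_rms`, `mqrank_z`. Missing columns behave as
#'   all-missing annotations.
#' @param config A [variant_filter_config()].
#' @return A list: `variants` (retained rows, with a `filter` column set to
#'   `PASS`), `rejected` (rows with the semicolon-joined names of the rules
#'   that fired), and `counts` (tibble `rule`, `n_rejected`,
#'   `n_not_applied`).
#' @export
hard_filter <- function(variants, config = variant_filter_config()) {
  v <- tibble::as_tibble(variants)
  if (!"type" %in% names(v)) v$type <- variant_type(v$ref, v$alt)
  col <- function(nm) if (nm %in% names(v)) v[[nm]] else rep(NA_real_,
                                                             nrow(v))
  is_snp <- v$type == "SNP"
  rules <- list(
    low_depth = list(val = col("depth"),
                     fire = function(x, s) x < config$min_depth),
    strand_bias = list(val = col("fs"),
                       fire = function(x, s) ifelse(s, x > config$max_fs_snp,
                                                    x > config$max_fs_indel)),
    read_position = list(val = col("readpos_z"),
                         fire = function(x, s)
                           ifelse(s, x < config$min_readpos_z_snp,
                                  x < config$min_readpos_z_indel)),
    mapping_quality = list(val = ifelse(is_snp, col("mq_rms"), NA_real_),
                           fire = function(x, s) s & x < config$min_mq_rms_snp),
    mq_rank_sum = list(val = ifelse(is_snp, col("mqrank_z"), NA_real_),
                       fire = function(x, s) s & x < config$min_mqrank_z_snp))
  fired <- matrix(FALSE, nrow(v), length(rules),
                  dimnames = list(NULL, names(rules)))
  skipped <- integer(length(rules))
  names(skipped) <- names(rules)
  for (r in names(rules)) {
    val <- rules[[r]]$val
    applicable <- !is.na(val)
    # mapping-quality rules never apply to indels; do not count those skips
    relevant <- if (r %in% c("mapping_quality", "mq_rank_sum")) is_snp
      else rep(TRUE, nrow(v))
    skipped[r] <- sum(relevant & !applicable)
    f <- rules[[r]]$fire(val, is_snp)
    fired[, r] <- applicable & !is.na(f) & f
  }
  reject <- rowSums(fired) > 0L
  reasons <- apply(fired, 1L, function(z)
    paste(names(rules)[z], collapse = ";"))
  list(
    variants = dplyr::mutate(v[!reject, , drop = FALSE], filter = "PASS"),
    rejected = dplyr::mutate(v[reject, , drop = FALSE],
                             filter = reasons[reject]),
    counts = tibble::tibble(rule = names(rules),
                            n_rejected = colSums(fired),
                            n_not_applied = unname(skipped)))
}

#' Variants present in every carrier and absent from every non-carrier
#'
#' Strict mode: the alternate allele must be present (>= 1 copy) in every
#' carrier and absent (0 copies) in every non-carrier; a missing genotype in
#' either group disqualifies the variant.
#'
#' @param genotypes Variants x samples alt-dosage matrix (0/1/2, `NA`
#'   missing) with row and column names.
#' @param carrier_ids,noncarrier_ids Sample IDs of duplication carriers and
#'   non-carriers.
#' @return Character vector of carrier-exclusive variant row names.
#' @export
carrier_exclusive <- function(genotypes, carrier_ids, noncarrier_ids) {
  if (length(carrier_ids) == 0L) stop_bad_arg("empty carrier set")
  unknown <- setdiff(c(carrier_ids, noncarrier_ids), colnames(genotypes))
  if (length(unknown) > 0L)
    stop_bad_arg("samples not in genotype matrix: %s",
                 paste(unknown, collapse = ", "))
  gc_ <- genotypes[, carrier_ids, drop = FALSE]
  gn <- genotypes[, noncarrier_ids, drop = FALSE]
  in_all_carriers <- rowSums(!is.na(gc_) & gc_ >= 1L) == length(carrier_ids)
  absent_noncarriers <- rowSums(!is.na(gn) & gn == 0L) ==
    length(noncarrier_ids)
  rownames(genotypes)[in_all_carriers & absent_noncarriers]
}

#' A minimal gene model for consequence classification
#'
#' @param gene_id Gene name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Tibbles/data frames with 1-based inclusive `start`,
#'   `end` (genomic, ascending); `cds` may be empty for non-coding genes.
#' @param seq Reference sequence (character string) covering the gene.
#' @param seq_start Genomic position of the first base of `seq`.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds = NULL, seq = NULL,
                       seq_start = 1L) {
  if (!strand %in% c("+", "-")) stop_bad_arg("strand must be '+' or '-'")
  exons <- tibble::as_tibble(exons)[order(exons$start), ]
  cds <- if (is.null(cds) || nrow(cds) == 0L)
    tibble::tibble(start = integer(), end = integer())
    else tibble::as_tibble(cds)[order(cds$start), ]
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 cds = cds, seq = seq, seq_start = as.integer(seq_start)),
            class = "gene_model")
}

in_any <- function(pos, tab) {
  any(tab$start <= pos & pos <= tab$end)
}

base_at <- function(model, gpos) {
  substr(model$seq, gpos - model$seq_start + 1L, gpos - model$seq_start + 1L)
}

comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify a variant against a gene model
#'
#' Interval containment decides the region class (`CDS`, `UTR5`, `UTR3`,
#' `intron`, `intergenic`); for CDS SNPs the reference and alternate codons
#' are translated with the standard genetic code (strand-aware) and the
#' variant is flagged synonymous when the amino acid is unchanged. A variant
#' whose alleles span a CDS/intron boundary is classified `CDS` with a
#' boundary flag.
#'
#' @param variant A one-row data frame or list with `pos`, `ref`, `alt`.
#' @param model A [gene_model()] (or list of them; the highest-priority
#'   class across genes wins).
#' @return Tibble: `pos`, `class`, `gene_id`, `synonymous` (NA unless a CDS
#'   SNP), `boundary`.
#' @export
classify_consequence <- function(variant, model) {
  if (inherits(model, "gene_model")) model <- list(model)
  pos <- variant$pos
  ref <- variant$ref
  alt <- variant$alt
  span_end <- pos + max(nchar(ref), 1L) - 1L
  res <- purrr::map_dfr(model, function(g) {
    gene_span <- range(c(g$exons$start, g$exons$end))
    overlaps_cds <- nrow(g$cds) > 0L &&
      any(g$cds$start <= span_end & pos <= g$cds$end)
    inside_cds <- overlaps_cds && in_any(pos, g$cds) &&
      in_any(span_end, g$cds)
    boundary <- overlaps_cds && !inside_cds
    cls <- if (overlaps_cds) "CDS"
      else if (in_any(pos, g$exons)) {
        if (nrow(g$cds) == 0L) "UTR5"
        else {
          before_cds <- pos < min(g$cds$start)
          if ((g$strand == "+") == before_cds) "UTR5" else "UTR3"
        }
      }
      else if (pos >= gene_span[1] && pos <= gene_span[2]) "intron"
      else "intergenic"
    syn <- NA
    if (cls == "CDS" && !boundary && nchar(ref) == 1L && nchar(alt) == 1L &&
        !is.null(g$seq)) {
      syn <- is_synonymous(g, pos, alt)
    }
    tibble::tibble(pos = pos, class = cls, gene_id = g$gene_id,
                   synonymous = syn, boundary = boundary)
  })
  pri <- c(CDS = 1, UTR5 = 2, UTR3 = 2, intron = 3, intergenic = 4)
  res[order(pri[res$class]), ][1L, ]
}

# translate the codon containing gpos with and without the alternate base
is_synonymous <- function(g, gpos, alt) {
  cds_pos <- unlist(purrr::map2(g$cds$start, g$cds$end, seq))
  if (g$strand == "-") cds_pos <- rev(cds_pos)
  i <- match(gpos, cds_pos)
  if (is.na(i)) return(NA)
  codon_idx <- (i - 1L) %/% 3L
  cpos <- cds_pos[codon_idx * 3L + 1:3]
  get_base <- function(p, use_alt) {
    b <- if (use_alt && p == gpos) alt else base_at(g, p)
    if (g$strand == "-") unname(comp[toupper(b)]) else toupper(b)
  }
  ref_codon <- paste0(get_base(cpos[1], FALSE), get_base(cpos[2], FALSE),
                      get_base(cpos[3], FALSE))
  alt_codon <- paste0(get_base(cpos[1], TRUE), get_base(cpos[2], TRUE),
                      get_base(cpos[3], TRUE))
  code <- Biostrings::GENETIC_CODE
  unname(code[ref_codon] == code[alt_codon])
}
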