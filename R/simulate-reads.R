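#' Configuration for the paired-end read simulator
#'
#' @param reference_length Reference (single contig) length in bp.
#' @param dup_start,dup_end 1-based inclusive interval of the tandem
#'   duplication on the reference; the default length is 98,607 bp.
#' @param mean_depth Total fold coverage of the diploid sample.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Outer fragment (insert) size distribution in
#'   bp; `insert_mean` must exceed `2 * read_length`.
#' @param seed Integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(reference_length = 500000L,
                            dup_start = 200001L,
                            dup_end = 298607L,
                            mean_depth = 20,
                            read_length = 100L,
                            insert_mean = 350,
                            insert_sd = 30,
                            seed = 1L) {
  reference_length <- check_count(reference_length, "reference_length")
  dup_start <- check_count(dup_start, "dup_start")
  dup_end <- check_count(dup_end, "dup_end")
  if (!(1L <= dup_start && dup_start < dup_end && dup_end <= reference_length))
    stop_bad_arg("need 1 <= dup_start < dup_end <= reference_length")
  read_length <- check_count(read_length, "read_length", min = 20L)
  if (insert_mean <= 2 * read_length)
    stop_bad_arg("insert_mean (%g) must exceed 2 * read_length (%d)",
                 insert_mean, 2L * read_length)
  if (mean_depth <= 0 || insert_sd < 0)
    stop_bad_arg("mean_depth must be > 0 and insert_sd >= 0")
  structure(list(reference_length = reference_length, dup_start = dup_start,
                 dup_end = dup_end, mean_depth = mean_depth,
                 read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate paired-end alignments over a reference with a tandem duplication
#'
#' Fragments are drawn uniformly from each of the two donor haplotypes (0, 1
#' or 2 of which carry a head-to-tail duplication of
#' `[dup_start, dup_end]`) and their reads are mapped back to reference
#' coordinates. Fragments crossing the duplication junction yield pairs whose
#' reads map in opposite orientation (reverse read left, forward read right)
#' roughly a duplication length apart on the reference - the tandem
#' duplication junction signature. Depth inside the duplicated interval is
#' elevated in proportion to copy number.
#'
#' @param config A [read_sim_config()].
#' @param copies Number of duplication-bearing haplotypes: 0, 1 or 2.
#' @return A tibble of read alignments sorted by leftmost coordinate, one row
#'   per read: `qname`, `flag` (SAM flag), `rname`, `pos`, `end`, `strand`,
#'   `cigar`, `mpos`, `mate_strand`, `tlen`, `read_len`.
#' @export
simulate_read_alignments <- function(config, copies = 1L) {
  stopifnot(inherits(config, "read_sim_config"))
  if (!copies %in% 0:2)
    stop_bad_arg("copies must be 0, 1 or 2, got %s", format(copies))
  rl <- config$read_length
  dlen <- config$dup_end - config$dup_start + 1L
  cov_hap <- config$mean_depth / 2

  sim_hap <- function(has_dup, hap_id, seed) {
    donor_len <- config$reference_length + if (has_dup) dlen else 0L
    n_frag <- round(cov_hap * donor_len / (2 * rl))
    with_seed(seed, {
      fl <- pmax(2L * rl, round(rnorm(n_frag, config$insert_mean,
                                      config$insert_sd)))
      s <- floor(runif(n_frag, 1, donor_len - fl + 1 + 1))
      d1 <- s                      # donor start, forward read
      d2 <- s + fl - rl            # donor start, reverse read
      # donor layout: copy1 = ref[1..dup_end], copy2 = ref[dup_start..dup_end]
      # head-to-tail, then the remainder; every donor base past dup_end maps
      # back by one duplication length
      r1 <- if (has_dup) ifelse(d1 > config$dup_end, d1 - dlen, d1) else d1
      r2 <- if (has_dup) ifelse(d2 > config$dup_end, d2 - dlen, d2) else d2
      tibble::tibble(
        qname = sprintf("frag_%s_%06d", hap_id, seq_len(n_frag)),
        r1 = as.integer(r1), r2 = as.integer(r2))
    })
  }

  haps <- list(sim_hap(copies >= 1L, "h1", derive_seed(config$seed, "reads")),
               sim_hap(copies >= 2L, "h2",
                       derive_seed(config$seed, "reads") + 1L))
  frags <- dplyr::bind_rows(haps)

  # emit one row per read, SAM flags under the FR-library convention:
  # read1 forward / read2 reverse in donor space, strands preserved by the
  # mapping, so junction-crossing pairs come out everted (RF) on the
  # reference
  mk <- function(pos, strand, mpos, mstrand, first) {
    flag <- 1L +                                  # paired
      ifelse(strand == "-", 16L, 0L) +
      ifelse(mstrand == "-", 32L, 0L) +
      ifelse(first, 64L, 128L)
    # proper-pair bit for concordant FR pairs at plausible insert
    lo <- pmin(pos, mpos); hi <- pmax(pos, mpos)
    fwd_left <- (pos <= mpos & strand == "+") | (mpos < pos & mstrand == "+")
    span <- hi + rl - lo
    proper <- fwd_left & strand != mstrand &
      span <= config$insert_mean + 10 * max(config$insert_sd, 1)
    flag + ifelse(proper, 2L, 0L)
  }
  reads <- dplyr::bind_rows(
    tibble::tibble(qname = frags$qname, pos = frags$r1, strand = "+",
                   mpos = frags$r2, mate_strand = "-", first = TRUE),
    tibble::tibble(qname = frags$qname, pos = frags$r2, strand = "-",
                   mpos = frags$r1, mate_strand = "+", first = FALSE))
  reads <- dplyr::mutate(
    reads,
    flag = mk(.data$pos, .data$strand, .data$mpos, .data$mate_strand,
              .data$first),
    rname = "chrS", end = .data$pos + rl - 1L, cigar = paste0(rl, "M"),
    tlen = dplyr::if_else(.data$pos <= .data$mpos,
                          .data$mpos + rl - .data$pos,
                          -(.data$pos + rl - .data$mpos)),
    read_len = rl)
  out <- dplyr::arrange(reads, .data$pos, .data$qname)
  dplyr::select(out, "qname", "flag", "rname", "pos", "end", "strand",
                "cigar", "mpos", "mate_strand", "tlen", "read_len")
}
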