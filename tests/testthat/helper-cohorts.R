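# shared builders for small test objects

tiny_cohort <- function(n_dogs = 200, n_markers = 60, seed = 1, ...) {
  simulate_cohort(population_config(n_dogs = n_dogs, n_markers = n_markers,
                                    n_background_markers = 50, seed = seed,
                                    ...))
}

# dosage table expanded from 2x2 counts (carrier/noncarrier x blue/brown)
dosages_from_counts <- function(carrier_blue, noncarrier_blue, carrier_brown,
                                noncarrier_brown) {
  tibble::tibble(
    copies = rep(c(1L, 0L, 1L, 0L),
                 c(carrier_blue, noncarrier_blue, carrier_brown,
                   noncarrier_brown)),
    phenotype = rep(c(1L, 1L, 0L, 0L),
                    c(carrier_blue, noncarrier_blue, carrier_brown,
                      noncarrier_brown)))
}

# everted read pairs (one row per read) with left reverse-read starts and
# right forward mate starts, as a tandem-duplication junction produces
everted_pairs <- function(left_starts, right_starts, read_len = 100L) {
  n <- length(left_starts)
  dplyr::bind_rows(
    tibble::tibble(qname = sprintf("p%03d", seq_len(n)), flag = 81L,
                   rname = "chrS", pos = as.integer(left_starts),
                   end = as.integer(left_starts) + read_len - 1L,
                   strand = "-", cigar = paste0(read_len, "M"),
                   mpos = as.integer(right_starts), mate_strand = "+",
                   tlen = 0L, read_len = read_len),
    tibble::tibble(qname = sprintf("p%03d", seq_len(n)), flag = 161L,
                   rname = "chrS", pos = as.integer(right_starts),
                   end = as.integer(right_starts) + read_len - 1L,
                   strand = "+", cigar = paste0(read_len, "M"),
                   mpos = as.integer(left_starts), mate_strand = "-",
                   tlen = 0L, read_len = read_len))
}

# single-linkage clustering oracle by explicit union-find over all pairs
cluster_oracle <- function(left, right, slop) {
  n <- length(left)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(left[i] - left[j]) <= slop && abs(right[i] - right[j]) <= slop) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# tiny phased haplotype array with dimnames
hap_array <- function(h1, h2, ids = NULL, marker_ids = NULL) {
  stopifnot(dim(h1)[1] == dim(h2)[1])
  n <- nrow(h1); m <- ncol(h1)
  ids <- ids %||% sprintf("dog%02d", seq_len(n))
  marker_ids <- marker_ids %||% sprintf("snp%02d", seq_len(m))
  a <- array(NA_integer_, c(n, 2L, m),
             dimnames = list(ids, c("h1", "h2"), marker_ids))
  a[, 1L, ] <- h1; a[, 2L, ] <- h2
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x
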