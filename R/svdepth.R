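# Tandem-duplication detection from alignments: scaled sliding-window read
# depth, opposite-orientation (everted) discordant-pair clustering, and a
# joint depth + junction call.

# per-base depth over [region_start, region_end] from a read-level alignment
# tibble; each read covers [pos, end] once
per_base_depth <- function(alignments, region_start, region_end) {
  stopifnot(is.data.frame(alignments), all(c("pos", "end") %in%
                                           names(alignments)))
  keep <- alignments$end >= region_start & alignments$pos <= region_end
  a <- alignments[keep, ]
  ir <- IRanges::IRanges(pmax(a$pos, region_start) - region_start + 1L,
                         pmin(a$end, region_end) - region_start + 1L)
  as.numeric(IRanges::coverage(ir,
                               width = region_end - region_start + 1L))
}

as_depth_vector <- function(x, region) {
  if (is.numeric(x)) {
    if (length(x) != region[2] - region[1] + 1)
      stop_bad_arg("depth vector length (%d) does not match region width (%d)",
                   length(x), region[2] - region[1] + 1)
    return(x)
  }
  per_base_depth(x, region[1], region[2])
}

#' Scaled sliding-window read depth
#'
#' Aggregates per-base depth into sliding windows and scales each window's
#' mean by the sample's mean depth across the whole region, so a diploid
#' background sits at 1 and a heterozygous/homozygous duplication at about
#' 1.5/2.
#'
#' @param x Either a read-level alignment tibble (as returned by
#'   [simulate_read_alignments()] or [read_alignments()]) or a per-base depth
#'   vector covering `region`.
#' @param region Length-2 integer vector `c(start, end)`, 1-based inclusive.
#' @param window_bp Window width in bp (default 10 kb).
#' @param step_bp Step between window starts (default 2,500 bp, i.e. 4x
#'   overlapping windows).
#' @return A tibble with `window_start`, `window_end`, `raw_mean_depth` and
#'   `scaled_depth`.
#' @export
scaled_window_depth <- function(x, region, window_bp = 10000L,
                                step_bp = 2500L) {
  window_bp <- check_count(window_bp, "window_bp")
  step_bp <- check_count(step_bp, "step_bp")
  if (window_bp < step_bp)
    stop_bad_arg("window_bp (%d) must be >= step_bp (%d)", window_bp, step_bp)
  depth <- as_depth_vector(x, region)
  total <- sum(depth)
  if (total == 0) stop_bad_arg("zero total depth in region; cannot scale")
  overall_mean <- total / length(depth)
  starts <- seq.int(1L, length(depth) - window_bp + 1L, by = step_bp)
  cs <- c(0, cumsum(depth))
  raw <- (cs[starts + window_bp] - cs[starts]) / window_bp
  tibble::tibble(window_start = region[1] + starts - 1L,
                 window_end = region[1] + starts + window_bp - 2L,
                 raw_mean_depth = raw,
                 scaled_depth = raw / overall_mean)
}

#' Cluster opposite-orientation (everted) discordant read pairs
#'
#' A pair is in "opposite orientation" when, on the reference, its leftmost
#' read is on the reverse strand and its rightmost read on the forward
#' strand (the RF/everted signature of a tandem-duplication junction under
#' an FR library). Pairs are grouped by single-linkage: two pairs join a
#' cluster when both their left-read starts and their mate starts are within
#' `max_span_slop_bp`.
#'
#' @param alignments Read-level alignment tibble with `qname`, `pos`,
#'   `strand`, `mpos`, `mate_strand` (one row per read; only the leftmost
#'   read of each pair is used).
#' @param min_support Minimum supporting pairs per reported cluster.
#' @param max_span_slop_bp Single-linkage distance in bp.
#' @return Tibble of clusters: `left_start`, `left_end` (span of left read
#'   starts), `right_start`, `right_end` (span of mate starts), `support`,
#'   `orientation`.
#' @export
find_discordant_clusters <- function(alignments, min_support = 3L,
                                     max_span_slop_bp = 10000L) {
  need <- c("qname", "pos", "strand", "mpos", "mate_strand")
  if (!all(need %in% names(alignments)))
    stop_bad_arg("alignments must have columns %s",
                 paste(need, collapse = ", "))
  a <- alignments
  bad <- !complete.cases(a[, need]) | !a$strand %in% c("+", "-") |
    !a$mate_strand %in% c("+", "-")
  if (any(bad)) {
    rlang::warn(sprintf("skipped %d reads with malformed pairing fields",
                        sum(bad)))
    a <- a[!bad, ]
  }
  # leftmost read of each pair; everted = reverse read left, forward right
  left <- a[a$pos < a$mpos & a$strand == "-" & a$mate_strand == "+", ]
  empty <- tibble::tibble(left_start = integer(), left_end = integer(),
                          right_start = integer(), right_end = integer(),
                          support = integer(), orientation = character())
  if (nrow(left) == 0L) return(empty)
  left <- left[order(left$pos, left$mpos), ]
  n <- nrow(left)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && left$pos[j] - left$pos[i] <= max_span_slop_bp) {
      if (abs(left$mpos[j] - left$mpos[i]) <= max_span_slop_bp) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(root = root, pos = left$pos,
                                   mpos = left$mpos), .data$root),
    left_start = min(.data$pos), left_end = max(.data$pos),
    right_start = min(.data$mpos), right_end = max(.data$mpos),
    support = dplyr::n(), .groups = "drop")
  out <- dplyr::filter(out, .data$support >= min_support)
  out <- dplyr::arrange(out, .data$left_start)
  dplyr::mutate(dplyr::select(out, -"root"), orientation = "opposite")
}

#' Read-depth ratio between a candidate duplication and its flanks
#'
#' Mean depth inside the interval divided by mean depth over up to `flank_bp`
#' of sequence on each side (clipped to the available region).
#'
#' @inheritParams scaled_window_depth
#' @param dup_interval Length-2 vector `c(start, end)`, 1-based inclusive.
#' @param flank_bp Flank width on each side in bp (default 5 Mb).
#' @return A single fold-change value.
#' @export
depth_ratio <- function(x, dup_interval, region, flank_bp = 5e6) {
  depth <- as_depth_vector(x, region)
  ds <- dup_interval[1] - region[1] + 1L
  de <- dup_interval[2] - region[1] + 1L
  if (ds < 1L || de > length(depth) || ds > de)
    stop_bad_arg("dup_interval outside region")
  lf <- max(1L, ds - as.integer(flank_bp)):max(1L, ds - 1L)
  rf <- min(length(depth), de + 1L):min(length(depth), de + as.integer(flank_bp))
  flank_idx <- unique(c(if (ds > 1L) lf, if (de < length(depth)) rf))
  if (length(flank_idx) == 0L || mean(depth[flank_idx]) == 0)
    stop_bad_arg("zero flank depth; ratio undefined")
  mean(depth[ds:de]) / mean(depth[flank_idx])
}

#' Call a tandem duplication from depth and discordant-pair evidence
#'
#' A call is made where an opposite-orientation cluster with sufficient
#' support coincides with elevated scaled depth. Breakpoints follow the
#' discordant-pair convention: `start` is the leftmost read start of the left
#' span and `end` the leftmost mate start of the right span (the first base
#' after the duplicated segment), so `length = end - start`. The depth ratio
#' is the mean scaled depth of windows inside the called interval over the
#' mean of windows outside it, and sets the copy class.
#'
#' @param profile A [scaled_window_depth()] tibble for the same sample and
#'   region as `clusters`.
#' @param clusters A [find_discordant_clusters()] tibble.
#' @param min_support Minimum supporting pairs.
#' @param min_ratio Minimum depth ratio to call (default 1.4).
#' @param het_range,hom_range Depth-ratio intervals assigned to the
#'   heterozygous (`[1.4, 1.75)`) and homozygous (`[1.75, 2.25]`) classes;
#'   qualifying calls outside both are labelled `ambiguous`, as are
#'   overlapping conflicting calls.
#' @return Tibble of calls (possibly empty): `start`, `end`, `length`,
#'   `depth_ratio`, `support`, `copy_class`.
#' @export
call_tandem_duplication <- function(profile, clusters, min_support = 3L,
                                    min_ratio = 1.4,
                                    het_range = c(1.4, 1.75),
                                    hom_range = c(1.75, 2.25)) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          length = integer(), depth_ratio = numeric(),
                          support = integer(), copy_class = character())
  if (is.null(clusters) || nrow(clusters) == 0L) return(empty)
  cand <- dplyr::filter(clusters, .data$support >= min_support)
  if (nrow(cand) == 0L) return(empty)
  calls <- purrr::pmap_dfr(cand, function(left_start, right_start, support,
                                          ...) {
    start <- left_start
    end <- right_start
    inside <- profile$window_start >= start & profile$window_end <= end - 1L
    if (!any(inside) || all(inside)) return(NULL)
    ratio <- mean(profile$scaled_depth[inside]) /
      mean(profile$scaled_depth[!inside])
    if (!is.finite(ratio) || ratio < min_ratio) return(NULL)
    copy_class <- if (ratio >= het_range[1] && ratio < het_range[2]) "het"
      else if (ratio >= hom_range[1] && ratio <= hom_range[2]) "hom"
      else "ambiguous"
    tibble::tibble(start = start, end = end, length = end - start,
                   depth_ratio = ratio, support = as.integer(support),
                   copy_class = copy_class)
  })
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  calls <- dplyr::arrange(calls, .data$start)
  if (nrow(calls) > 1L) {
    # overlapping conflicting calls are reported, flagged ambiguous
    ov <- vapply(seq_len(nrow(calls)), function(i) any(
      calls$start[-i] < calls$end[i] & calls$end[-i] > calls$start[i]),
      logical(1))
    calls$copy_class[ov] <- "ambiguous"
  }
  calls
}
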