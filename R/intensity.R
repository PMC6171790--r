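# Duplication genotyping from SNP-array probe intensities: the delta log R
# statistic (mean log R at in-duplication markers minus mean at flanking
# markers), per-dog copy-number classification, and distribution comparisons
# between haplotype classes.

#' Per-dog delta log R
#'
#' `delta_logR = mean(log R at duplication markers) - mean(log R at flank
#' markers)`, with missing markers dropped from each mean and counted. A
#' per-marker z-score pattern inside the duplication flags dogs whose
#' duplication covers only part of the interval: `partial` when at least two
#' contiguous in-duplication markers look carrier-like and at least two look
#' non-carrier-like.
#'
#' @param intensities Dogs x markers log R matrix (dimnames required), or a
#'   tibble with a `dog_id` column followed by marker columns.
#' @param dup_markers Character vector of marker IDs inside the duplication.
#' @param flank_markers Character vector of flanking marker IDs (disjoint
#'   from `dup_markers`).
#' @param het_shift Expected heterozygous-carrier shift used only for the
#'   partial-pattern flag (markers are carrier-like above `het_shift / 2`).
#' @param sigma Per-marker noise SD used for the partial-pattern z-scores.
#' @return A tibble with one row per dog: `dog_id`, `delta_logR`,
#'   `n_dup_markers`, `n_flank_markers`, `partial_pattern`.
#' @export
delta_logR <- function(intensities, dup_markers, flank_markers,
                       het_shift = 0.35, sigma = 0.12) {
  if (is.data.frame(intensities)) {
    ids <- intensities$dog_id
    intensities <- as.matrix(intensities[setdiff(names(intensities),
                                                 "dog_id")])
    rownames(intensities) <- ids
  }
  if (length(intersect(dup_markers, flank_markers)) > 0L)
    stop_bad_arg("dup_markers and flank_markers must be disjoint")
  missing_cols <- setdiff(c(dup_markers, flank_markers),
                          colnames(intensities))
  if (length(missing_cols) > 0L)
    stop_bad_arg("markers not in intensity matrix: %s",
                 paste(head(missing_cols, 5L), collapse = ", "))
  dup <- intensities[, dup_markers, drop = FALSE]
  fl <- intensities[, flank_markers, drop = FALSE]
  n_dup <- rowSums(!is.na(dup))
  n_fl <- rowSums(!is.na(fl))
  delta <- rowMeans(dup, na.rm = TRUE) - rowMeans(fl, na.rm = TRUE)
  delta[n_dup == 0L | n_fl == 0L] <- NA_real_

  # per-marker z-calls inside the interval: carrier-like when clearly above
  # the diploid baseline (z >= 2), non-carrier-like when clearly below the
  # heterozygote level (z <= -2); a dog is flagged partial when both states
  # occur in runs of >= 2 contiguous markers
  carrier_like <- dup > 2 * sigma
  nonc_like <- dup < het_shift - 2 * sigma
  has_run <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    r <- rle(x)
    any(r$lengths[r$values] >= 2L)
  }
  partial <- vapply(seq_len(nrow(dup)), function(i) {
    if (sum(!is.na(dup[i, ])) < 4L) return(FALSE)
    has_run(carrier_like[i, ]) && has_run(nonc_like[i, ])
  }, logical(1))

  tibble::tibble(dog_id = rownames(intensities) %||%
                   paste0("dog", seq_len(nrow(intensities))),
                 delta_logR = unname(delta),
                 n_dup_markers = as.integer(n_dup),
                 n_flank_markers = as.integer(n_fl),
                 partial_pattern = partial)
}

#' Copy-number class from delta log R
#'
#' Thresholds follow the carrier-calling rule delta log R > 0.15 (strictly
#' greater; a dog at exactly the threshold is a non-carrier): 0 copies up to
#' `het_threshold`, 1 copy in `(het_threshold, hom_threshold]`, 2 copies
#' above. Dogs with a partial in-duplication pattern are labelled
#' `partial`; dogs with no usable delta are `unknown`.
#'
#' @param profile A [delta_logR()] tibble (or any data frame with
#'   `delta_logR` and optionally `partial_pattern`).
#' @param het_threshold Carrier bound (default 0.15).
#' @param hom_threshold Heterozygote/homozygote bound (default 0.5, the
#'   midpoint of the default per-copy shifts).
#' @return The profile with a `copy_class` column in
#'   `c("0", "1", "2", "partial", "unknown")`.
#' @export
genotype_from_delta <- function(profile, het_threshold = 0.15,
                                hom_threshold = 0.5) {
  if (!(0 < het_threshold && het_threshold < hom_threshold))
    stop_bad_arg("need 0 < het_threshold < hom_threshold")
  partial <- profile$partial_pattern %||% rep(FALSE, nrow(profile))
  delta <- profile$delta_logR
  cls <- dplyr::case_when(
    is.na(delta) ~ "unknown",
    partial ~ "partial",
    delta <= het_threshold ~ "0",
    delta <= hom_threshold ~ "1",
    TRUE ~ "2")
  dplyr::mutate(tibble::as_tibble(profile), copy_class = cls)
}

#' Compare delta log R distributions between two groups
#'
#' Two-sided rank-based two-sample test (Mann-Whitney U by default;
#' Kolmogorov-Smirnov available), as used to show that haplotype carriers
#' and non-carriers, or heterozygotes and homozygotes, have distinct
#' delta log R distributions.
#'
#' @param group_a,group_b Numeric vectors of delta log R values (each n >= 2).
#' @param method `"wilcox"` (Mann-Whitney U) or `"ks"`.
#' @return A tibble: `method`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_delta_distributions <- function(group_a, group_b,
                                        method = c("wilcox", "ks")) {
  method <- match.arg(method)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_bad_arg("each group needs at least 2 finite values")
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(method = method, statistic = NA_real_,
                          p_value = 1, n_a = length(group_a),
                          n_b = length(group_b)))
  }
  t <- if (method == "wilcox")
    suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE))
  else suppressWarnings(ks.test(group_a, group_b))
  tibble::tibble(method = method, statistic = unname(t$statistic),
                 p_value = t$p.value, n_a = length(group_a),
                 n_b = length(group_b))
}
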