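# broom-style tidiers for fitted objects

#' Tidy an LMM scan into a hit table
#'
#' @param x An `lmm_scan` from [lmm_wald_scan()].
#' @param ... Unused.
#' @return The per-marker tibble with a `tier` column, sorted by P.
#' @export
tidy.lmm_scan <- function(x, ...) {
  classify_hits(x, attr(x, "config"))
}

#' One-row summary of an LMM scan
#'
#' @param x An `lmm_scan`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_markers`, `n_tested`,
#'   `n_significant`, `n_suggestive`, `lambda_gc`, `top_marker`, `min_p`.
#' @export
glance.lmm_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  p <- x$p_wald[is.finite(x$p_wald)]
  top <- x$marker_id[which.min(x$p_wald)]
  tibble::tibble(
    n_samples = attr(x, "n"),
    n_markers = nrow(x),
    n_tested = sum(x$ok),
    n_significant = sum(p < cfg$significant_threshold),
    n_suggestive = sum(p < cfg$suggestive_threshold &
                         p >= cfg$significant_threshold),
    lambda_gc = if (length(p) >= 2L) qq_data(p)$lambda_gc else NA_real_,
    top_marker = if (length(top)) top else NA_character_,
    min_p = if (length(p)) min(p) else NA_real_)
}

#' @export
tidy.qq_data <- function(x, ...) x$points

#' @export
glance.qq_data <- function(x, ...) {
  tibble::tibble(n_pvalues = nrow(x$points), lambda_gc = x$lambda_gc)
}
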