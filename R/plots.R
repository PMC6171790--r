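# ggplot2 display helpers for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of an association scan
#'
#' @param object An `lmm_scan`, optionally with marker positions supplied.
#' @param positions Optional bp positions aligned with the scan rows.
#' @param config A [gwas_config()] for the threshold lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lmm_scan <- function(object, positions = NULL,
                              config = attr(object, "config"), ...) {
  df <- tibble::as_tibble(object)
  df$x <- positions %||% seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p_wald))) +
    ggplot2::geom_point(size = 0.6, colour = "grey30", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(config$suggestive_threshold),
                        colour = "grey60", linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(config$significant_threshold),
                        colour = "black", linetype = 2) +
    ggplot2::labs(x = if (is.null(positions)) "marker index"
                    else "position (bp)",
                  y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' @param object A [qq_data()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qq_data <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(P))),
      y = expression(Observed ~ -log[10](italic(P))),
      subtitle = sprintf("lambda[GC] = %.3f", object$lambda_gc)) +
    ggplot2::theme_minimal()
}

#' Scaled read-depth profile with optional call overlay
#'
#' @param profile A [scaled_window_depth()] tibble.
#' @param calls Optional [call_tandem_duplication()] tibble.
#' @return A ggplot.
#' @export
plot_depth_profile <- function(profile, calls = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (.data$window_start +
                                           .data$window_end) / 2,
                                    y = .data$scaled_depth)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60", linetype = 2) +
    ggplot2::labs(x = "position (bp)", y = "scaled depth") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0L)
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.15)
  p
}

#' Density plot of delta log R by copy-number class
#'
#' @param profile A [genotype_from_delta()] tibble.
#' @return A ggplot.
#' @export
plot_delta_logr <- function(profile) {
  df <- profile[is.finite(profile$delta_logR), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_logR,
                                   fill = .data$copy_class)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::geom_rug(ggplot2::aes(colour = .data$copy_class), sides = "b",
                      alpha = 0.5, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(x = expression(Delta ~ log ~ R), y = "density") +
    ggplot2::theme_minimal()
}
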