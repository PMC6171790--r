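# Mixed-model association scan: QC filters, centered-genotype relatedness
# matrix, per-marker ML estimation of the variance ratio on the
# eigen-rotated model, Wald tests, and hit classification.

#' GWAS configuration
#'
#' @param significant_threshold Genome-wide significance threshold on the
#'   Wald P (default 5e-8, strict `<`).
#' @param suggestive_threshold Suggestive threshold (default 1e-5).
#' @param max_missing_per_dog Maximum fraction of missing genotypes per
#'   sample (default 0.025).
#' @param min_call_rate_per_marker Minimum fraction of genotyped samples per
#'   marker (default 0.95).
#' @return A list of class `gwas_config`.
#' @export
gwas_config <- function(significant_threshold = 5e-8,
                        suggestive_threshold = 1e-5,
                        max_missing_per_dog = 0.025,
                        min_call_rate_per_marker = 0.95) {
  if (!(suggestive_threshold > significant_threshold))
    stop_bad_arg("suggestive_threshold (%g) must exceed significant_threshold (%g)",
                 suggestive_threshold, significant_threshold)
  check_fraction(max_missing_per_dog, "max_missing_per_dog")
  check_fraction(min_call_rate_per_marker, "min_call_rate_per_marker")
  structure(list(significant_threshold = significant_threshold,
                 suggestive_threshold = suggestive_threshold,
                 max_missing_per_dog = max_missing_per_dog,
                 min_call_rate_per_marker = min_call_rate_per_marker),
            class = "gwas_config")
}

#' Sample- and marker-level genotype QC
#'
#' Samples exceeding the per-sample missingness bound are removed first,
#' then markers falling below the per-marker call rate (computed on the
#' retained samples).
#'
#' @param genotypes Samples x markers dosage matrix, `NA` = missing.
#' @param config A [gwas_config()].
#' @return A list: `genotypes` (filtered matrix) and `report`, a tibble with
#'   one row per filtering step (`step`, `removed`, `kept`).
#' @export
qc_filter <- function(genotypes, config = gwas_config()) {
  stopifnot(is.matrix(genotypes))
  miss_dog <- rowMeans(is.na(genotypes))
  keep_dog <- miss_dog <= config$max_missing_per_dog
  g1 <- genotypes[keep_dog, , drop = FALSE]
  call_rate <- colMeans(!is.na(g1))
  keep_marker <- call_rate >= config$min_call_rate_per_marker
  g2 <- g1[, keep_marker, drop = FALSE]
  if (nrow(g2) == 0L || ncol(g2) == 0L)
    stop_bad_arg("no samples or markers left after QC filtering")
  list(genotypes = g2,
       report = tibble::tibble(
         step = c("samples_missingness", "marker_call_rate"),
         removed = c(sum(!keep_dog), sum(!keep_marker)),
         kept = c(sum(keep_dog), sum(keep_marker))))
}

#' Relatedness matrix from centered genotypes
#'
#' `K = Xc Xc' / p` over the `p` markers, where `Xc` is the column-centered
#' dosage matrix. Residual missing genotypes are mean-imputed per marker.
#'
#' @param genotypes Samples x markers dosage matrix.
#' @return A symmetric positive semi-definite samples x samples matrix with
#'   attribute `n_markers_used`.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(is.matrix(genotypes))
  p <- ncol(genotypes)
  if (p == 0L) stop_bad_arg("no markers; cannot build a relatedness matrix")
  X <- mean_impute(genotypes)
  Xc <- sweep(X, 2L, colMeans(X))
  K <- tcrossprod(Xc) / p
  K <- (K + t(K)) / 2
  attr(K, "n_markers_used") <- p
  K
}

mean_impute <- function(genotypes) {
  if (!anyNA(genotypes)) return(genotypes)
  mu <- colMeans(genotypes, na.rm = TRUE)
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  genotypes[idx] <- mu[idx[, 2L]]
  genotypes
}

#' Univariate linear mixed-model Wald scan
#'
#' Fits, per marker, `y = W a + x b + u + e` with `u ~ N(0, l/tau K)` and
#' `e ~ N(0, 1/tau I)`. The model is rotated by the eigenvectors of `K`
#' once; per marker the variance ratio `l` maximizes the profile ML
#' log-likelihood over a log-spaced grid on `[1e-5, 1e5]` refined by
#' golden-section search in the bracketing interval, and the effect, its
#' standard error and the Wald P come from generalized least squares at the
#' optimum, referred to F(1, n - c - 1) where `c` counts covariates
#' including the intercept. A binary phenotype is treated as quantitative.
#'
#' @param genotypes Samples x markers dosage matrix (post-QC; residual
#'   missingness mean-imputed).
#' @param phenotype Numeric vector (0/1 for case-control).
#' @param K Relatedness matrix from [compute_grm()]; computed from
#'   `genotypes` when omitted.
#' @param covariates Optional numeric matrix of extra covariates (an
#'   intercept is always included).
#' @param config A [gwas_config()] (thresholds are carried into the result).
#' @return An object of class `lmm_scan`: a tibble with one row per marker
#'   (`marker_id`, `beta`, `se`, `lambda`, `wald_stat`, `p_wald`, `ok`), with
#'   the sample size, covariate count and config as attributes. `tidy()`
#'   returns it with hit tiers, `glance()` scan-level summaries.
#' @export
lmm_wald_scan <- function(genotypes, phenotype, K = NULL, covariates = NULL,
                          config = gwas_config()) {
  stopifnot(is.matrix(genotypes))
  y <- as.numeric(phenotype)
  n <- nrow(genotypes)
  if (length(y) != n) stop_bad_arg("phenotype length != number of samples")
  X <- mean_impute(genotypes)
  if (is.null(K)) K <- compute_grm(X)
  W <- cbind(intercept = rep(1, n), covariates)
  c_ <- ncol(W)
  df <- n - c_ - 1L

  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  yt <- drop(Ut %*% y)
  Wt <- Ut %*% W
  Xt <- Ut %*% X

  loglam <- seq(-5, 5, by = 0.1)
  lam_grid <- 10^loglam
  L <- length(lam_grid)
  Vmat <- 1 / (outer(d, lam_grid) + 1)            # n x L weights
  logdet <- colSums(log(outer(d, lam_grid) + 1))

  # per-lambda covariate-side quantities
  Ainv <- vector("list", L)
  a_l <- matrix(0, c_, L)
  yy_l <- colSums(Vmat * yt^2)
  rss0 <- numeric(L)
  for (l in seq_len(L)) {
    v <- Vmat[, l]
    A <- crossprod(Wt, Wt * v)
    Ainv[[l]] <- solve(A)
    a_l[, l] <- crossprod(Wt, v * yt)
    rss0[l] <- yy_l[l] - drop(crossprod(a_l[, l], Ainv[[l]] %*% a_l[, l]))
  }

  p <- ncol(X)
  XX <- crossprod(Vmat, Xt^2)                      # L x p
  XY <- crossprod(Vmat, Xt * yt)                   # L x p
  XW <- lapply(seq_len(c_), function(j) crossprod(Vmat, Xt * Wt[, j]))

  # profile ML log-likelihood, up to marker-independent constants
  const <- 0.5 * (n * log(n / (2 * pi)) - n)
  ml_at <- function(lam, x) {
    v <- 1 / (lam * d + 1)
    A <- crossprod(Wt, Wt * v)
    Ai <- solve(A)
    a <- crossprod(Wt, v * yt)
    xw <- crossprod(Wt, v * x)
    xx <- sum(v * x^2)
    xy <- sum(v * x * yt)
    s <- xx - drop(crossprod(xw, Ai %*% xw))
    if (s <= 1e-10 * max(xx, 1e-300)) return(list(ll = -1e300))
    num <- xy - drop(crossprod(xw, Ai %*% a))
    rss <- sum(v * yt^2) - drop(crossprod(a, Ai %*% a)) - num^2 / s
    if (rss <= 0) return(list(ll = -1e300))
    list(ll = const - 0.5 * sum(log(lam * d + 1)) - 0.5 * n * log(rss),
         beta = num / s, se2_unit = 1 / s, rss = rss)
  }

  res <- tibble::tibble(
    marker_id = colnames(X) %||% paste0("m", seq_len(p)),
    beta = NA_real_, se = NA_real_, lambda = NA_real_,
    wald_stat = NA_real_, p_wald = NA_real_, ok = TRUE)

  if (c_ == 1L) {
    ainv1 <- vapply(Ainv, function(x) x[1L, 1L], numeric(1))
    aa1 <- a_l[1L, ]
  }
  for (j in seq_len(p)) {
    xj <- Xt[, j]
    if (c_ == 1L) {
      s_all <- XX[, j] - XW[[1L]][, j]^2 * ainv1
      num_all <- XY[, j] - XW[[1L]][, j] * ainv1 * aa1
    } else {
      s_all <- XX[, j] - vapply(seq_len(L), function(l) {
        xw <- vapply(seq_len(c_), function(k) XW[[k]][l, j], numeric(1))
        drop(crossprod(xw, Ainv[[l]] %*% xw))
      }, numeric(1))
      num_all <- XY[, j] - vapply(seq_len(L), function(l) {
        xw <- vapply(seq_len(c_), function(k) XW[[k]][l, j], numeric(1))
        drop(crossprod(xw, Ainv[[l]] %*% a_l[, l]))
      }, numeric(1))
    }
    # collinear/monomorphic markers leave essentially no marker variance
    # after projecting out the covariates: flag, do not test
    valid <- s_all > 1e-10 * pmax(XX[, j], 1e-300)
    rss_all <- rss0 - ifelse(valid, num_all^2 / s_all, 0)
    valid <- valid & rss_all > 0
    if (!any(valid)) { res$ok[j] <- FALSE; next }
    ll <- ifelse(valid,
                 const - 0.5 * logdet - 0.5 * n * log(rss_all), -1e300)
    i <- which.max(ll)
    lo <- loglam[max(1L, i - 1L)]
    hi <- loglam[min(L, i + 1L)]
    opt <- optimize(function(z) ml_at(10^z, xj)$ll, c(lo, hi),
                    maximum = TRUE, tol = 1e-4)
    lam_hat <- 10^opt$maximum
    fit <- ml_at(lam_hat, xj)
    if (is.null(fit$beta) || fit$ll <= -1e299) { res$ok[j] <- FALSE; next }
    sigma2 <- fit$rss / df
    se <- sqrt(sigma2 * fit$se2_unit)
    fstat <- (fit$beta / se)^2
    res$beta[j] <- fit$beta
    res$se[j] <- se
    res$lambda[j] <- lam_hat
    res$wald_stat[j] <- fstat
    res$p_wald[j] <- pf(fstat, 1, df, lower.tail = FALSE)
  }

  structure(res, class = c("lmm_scan", class(res)),
            n = n, n_covariates = c_, config = config)
}

#' Classify association results into significance tiers
#'
#' Strict inequalities, following the convention that significance is
#' declared at `P < 5e-8` (a P equal to the threshold is not significant).
#'
#' @param results An `lmm_scan` or any data frame with a `p_wald` column.
#' @param config A [gwas_config()].
#' @return The table sorted by ascending P with a `tier` column in
#'   `significant`, `suggestive`, `none`.
#' @export
classify_hits <- function(results, config = gwas_config()) {
  if (nrow(results) == 0L) stop_bad_arg("empty results table")
  out <- dplyr::mutate(
    tibble::as_tibble(results),
    tier = dplyr::case_when(
      .data$p_wald < config$significant_threshold ~ "significant",
      .data$p_wald < config$suggestive_threshold ~ "suggestive",
      TRUE ~ "none"))
  dplyr::arrange(out, .data$p_wald)
}

#' Expected vs observed quantiles and the genomic inflation factor
#'
#' Expected quantiles are `-log10((i - 0.5) / m)`; the inflation factor
#' `lambda_GC` is the median observed 1-df chi-square quantile divided by
#' its null expectation (0.4549...).
#'
#' @param results An `lmm_scan`, data frame with `p_wald`, or numeric vector
#'   of p-values.
#' @return A list of class `qq_data`: `points` (tibble `expected`,
#'   `observed` in -log10 units) and `lambda_gc`.
#' @export
qq_data <- function(results) {
  p <- if (is.numeric(results)) results else results$p_wald
  p <- p[is.finite(p)]
  if (length(p) < 2L) stop_bad_arg("need at least 2 p-values")
  m <- length(p)
  obs <- sort(p)
  chisq_obs <- qchisq(p, df = 1, lower.tail = FALSE)
  structure(list(
    points = tibble::tibble(expected = -log10((seq_len(m) - 0.5) / m),
                            observed = -log10(obs)),
    lambda_gc = median(chisq_obs) / qchisq(0.5, df = 1)),
    class = "qq_data")
}

#' @export
print.qq_data <- function(x, ...) {
  cat(sprintf("<qq_data> %d p-values, lambda_GC = %.3f\n",
              nrow(x$points), x$lambda_gc))
  invisible(x)
}
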