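#' Per-copy-number log R intensity model
#'
#' Expected per-marker log R shift by total copy number of the probed locus
#' (2 = diploid baseline, 3 = heterozygous duplication carrier, 4 =
#' homozygous), plus iid per-marker Gaussian noise. Defaults place the
#' heterozygote shift at 0.35 and homozygote at 0.65, consistent with a
#' carrier calling bound of delta log R > 0.15 and typical array probe noise.
#'
#' @param mu_by_total_copies Named numeric vector over total copies
#'   `c("2" = 0, "3" = ..., "4" = ...)`; must be 0 at 2 and strictly
#'   increasing.
#' @param sigma_marker Per-marker noise SD (> 0).
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(mu_by_total_copies = c("2" = 0, "3" = 0.35,
                                                   "4" = 0.65),
                            sigma_marker = 0.12) {
  mu <- mu_by_total_copies
  if (is.null(names(mu))) names(mu) <- as.character(seq_along(mu) + 1L)
  if (!all(c("2", "3", "4") %in% names(mu)))
    stop_bad_arg("mu_by_total_copies must name total copies 2, 3 and 4")
  mu <- mu[c("2", "3", "4")]
  if (mu[["2"]] != 0) stop_bad_arg("mu_by_total_copies[\"2\"] must be 0")
  if (any(diff(mu) <= 0))
    stop_bad_arg("mu_by_total_copies must be strictly increasing")
  if (!is.numeric(sigma_marker) || sigma_marker <= 0)
    stop_bad_arg("sigma_marker must be > 0")
  structure(list(mu_by_total_copies = mu, sigma_marker = sigma_marker),
            class = "intensity_model")
}

#' Simulate SNP-array log R intensities for a cohort
#'
#' Markers inside the duplication interval receive the copy-number-dependent
#' shift `mu_by_total_copies[2 + dup_copies]`; all other markers are centred
#' at 0. Per-marker Gaussian noise is added everywhere. If the cohort carries
#' a partial-duplication dog, only the first half of its in-duplication
#' markers are shifted (heterozygote level), emulating a duplication covering
#' a prefix of the interval.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param model An [intensity_model()].
#' @param seed Integer seed; the matrix is deterministic given it.
#' @return A dogs x markers numeric matrix of log R values, with the cohort's
#'   dog and marker IDs as dimnames.
#' @export
simulate_intensities <- function(cohort, model = intensity_model(),
                                 seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(model, "intensity_model"))
  n <- nrow(cohort$dogs)
  m <- nrow(cohort$markers)
  in_dup <- cohort$markers$in_dup
  if (!any(in_dup))
    stop_bad_arg("cohort has no markers inside the duplication interval")
  key <- as.character(2L + cohort$dogs$dup_copies)
  bad <- !key %in% names(model$mu_by_total_copies)
  if (any(bad))
    stop_bad_arg("no intensity level for total copy number %s (dog %s)",
                 key[which(bad)[1]], cohort$dogs$dog_id[which(bad)[1]])
  mu <- matrix(0, n, m, dimnames = dimnames(cohort$genotypes))
  mu[, in_dup] <- rep(model$mu_by_total_copies[key], sum(in_dup))
  if (!is.na(cohort$partial_dog)) {
    i <- match(cohort$partial_dog, cohort$dogs$dog_id)
    dup_cols <- which(in_dup)
    keep <- dup_cols[seq_len(ceiling(length(dup_cols) / 2))]
    mu[i, in_dup] <- 0
    mu[i, keep] <- model$mu_by_total_copies[["3"]]
  }
  with_seed(derive_seed(seed, "intensity"), {
    mu + matrix(rnorm(n * m, sd = model$sigma_marker), n, m)
  })
}
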