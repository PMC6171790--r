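# internal helpers

stop_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "irisdup_error")
}

check_fraction <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok)
    stop_bad_arg("`%s` must be a single number in [0,%s], got %s",
                 name, if (allow_one) "1" else "1)", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_bad_arg("`%s` must be an integer >= %d, got %s", name, min, format(x))
  invisible(as.integer(x))
}

# Derive a stream-specific seed from a master seed so independent generators
# (genotypes, intensities, reads) do not reuse the same stream.  Kept below
# .Machine$integer.max.
derive_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, intensity = 101L, reads = 211L,
               phenotype = 307L, scan = 401L, variants = 503L)
  off <- unname(offsets[stream])
  if (is.na(off)) off <- 997L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
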