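# Core-haplotype fine-mapping: extract the haplotype shared by blue-eyed
# homozygotes around the duplication, define the core sub-haplotype, count
# core copies per dog excluding in-duplication markers, and run the
# haplotype-phenotype association, penetrance and modifier analyses.

hap_slice <- function(haplotypes, marker_ids) {
  stopifnot(length(dim(haplotypes)) == 3L)
  haplotypes[, , marker_ids, drop = FALSE]
}

#' Haplotype shared by case homozygotes around an index marker
#'
#' Starting at the index marker, at which every listed dog must be
#' homozygous for the same allele, the interval is extended left and right
#' one marker at a time: at each new marker a consensus allele is chosen
#' (the allele carried by the most surviving haplotypes; ties to the lower
#' code) and a haplotype survives while it matches the consensus at every
#' marker so far. Extension stops at the first marker where some dog has no
#' surviving haplotype for any allele.
#'
#' @param haplotypes Dogs x 2 x markers 0/1 array with dimnames (as in a
#'   [simulate_cohort()] or [read_genotypes_vcf()] result).
#' @param markers Tibble with `marker_id` and `pos` matching the array's
#'   third dimension.
#' @param case_ids Dog IDs of the case homozygotes.
#' @param index_pos Basepair position of the index (associated) marker.
#' @return A list of class `shared_haplotype`: `markers` (tibble
#'   `marker_id`, `pos`, `allele`), `span_start`, `span_end`, `index_pos`.
#' @export
find_shared_haplotype <- function(haplotypes, markers, case_ids, index_pos) {
  idx <- match(index_pos, markers$pos)
  if (is.na(idx)) stop_bad_arg("no marker at position %s", format(index_pos))
  ids <- match(case_ids, dimnames(haplotypes)[[1]])
  if (anyNA(ids))
    stop_bad_arg("unknown dog IDs: %s",
                 paste(case_ids[is.na(ids)], collapse = ", "))
  H <- haplotypes[ids, , , drop = FALSE]
  m <- dim(H)[3]
  a0 <- H[, 1L, idx]
  not_hom <- H[, 1L, idx] != H[, 2L, idx] | is.na(a0)
  if (any(not_hom) || length(unique(a0)) != 1L) {
    bad <- case_ids[not_hom | a0 != a0[1]]
    stop_bad_arg("dogs not homozygous for the index allele at %s: %s",
                 format(index_pos), paste(unique(bad), collapse = ", "))
  }
  consensus <- rep(NA_integer_, m)
  consensus[idx] <- a0[1]
  n_case <- length(ids)
  surv <- matrix(TRUE, n_case, 2L)

  step <- function(surv, j) {
    al <- matrix(H[, , j], ncol = 2L)    # n_case x 2
    best <- NULL; best_n <- -1L
    for (a in c(0L, 1L)) {
      ok_hap <- surv & !is.na(al) & al == a
      if (all(rowSums(ok_hap) >= 1L)) {
        n_surv <- sum(ok_hap)
        if (n_surv > best_n) { best <- a; best_n <- n_surv }
      }
    }
    if (is.null(best)) return(NULL)
    list(allele = best, surv = surv & !is.na(al) & al == best)
  }

  right <- idx; s <- surv
  while (right < m) {
    st <- step(s, right + 1L)
    if (is.null(st)) break
    right <- right + 1L; consensus[right] <- st$allele; s <- st$surv
  }
  left <- idx; s <- surv
  while (left > 1L) {
    st <- step(s, left - 1L)
    if (is.null(st)) break
    left <- left - 1L; consensus[left] <- st$allele; s <- st$surv
  }

  keep <- left:right
  structure(list(
    markers = tibble::tibble(marker_id = markers$marker_id[keep],
                             pos = markers$pos[keep],
                             allele = consensus[keep]),
    span_start = markers$pos[left], span_end = markers$pos[right],
    index_pos = index_pos), class = "shared_haplotype")
}

#' Define the core haplotype from the shared interval
#'
#' The core is the largest sub-interval of the shared interval, containing
#' the index marker, on which at least `min_two_copy_fraction` of the case
#' homozygotes carry two haplotypes matching the consensus at every marker.
#' Markers falling inside the duplication interval are recorded as excluded
#' (they are unreliable inside the duplication and are skipped when counting
#' copies in other dogs).
#'
#' @inheritParams find_shared_haplotype
#' @param shared A [find_shared_haplotype()] result.
#' @param min_two_copy_fraction Required two-copy fraction (default 0.9).
#' @param dup_interval Length-2 bp vector marking the duplication, or `NULL`.
#' @return A list of class `core_haplotype`: `markers` (tibble `marker_id`,
#'   `pos`, `allele`, `excluded`), `span_start`, `span_end`,
#'   `two_copy_fraction`.
#' @export
define_core <- function(haplotypes, case_ids, shared,
                        min_two_copy_fraction = 0.9, dup_interval = NULL) {
  stopifnot(inherits(shared, "shared_haplotype"))
  ids <- match(case_ids, dimnames(haplotypes)[[1]])
  H <- haplotypes[ids, , shared$markers$marker_id, drop = FALSE]
  m <- dim(H)[3]
  idx <- match(shared$index_pos, shared$markers$pos)
  cons <- shared$markers$allele
  h1 <- matrix(H[, 1L, ], nrow = length(ids))
  h2 <- matrix(H[, 2L, ], nrow = length(ids))
  match1 <- !is.na(h1) & h1 == rep(cons, each = length(ids))
  match2 <- !is.na(h2) & h2 == rep(cons, each = length(ids))
  row_cumsum <- function(M) {
    if (ncol(M) == 1L) cbind(0L, M * 1L)
    else cbind(0L, t(apply(M, 1L, cumsum)))
  }
  cum1 <- row_cumsum(match1)
  cum2 <- row_cumsum(match2)

  frac_two <- function(l, r) {
    w <- r - l + 1L
    mean(cum1[, r + 1L] - cum1[, l] == w & cum2[, r + 1L] - cum2[, l] == w)
  }
  best <- NULL
  for (l in seq_len(idx)) {
    for (r in idx:m) {
      f <- frac_two(l, r)
      if (f >= min_two_copy_fraction) {
        cand <- list(l = l, r = r, f = f, width = r - l + 1L)
        if (is.null(best) || cand$width > best$width) best <- cand
      }
    }
  }
  if (is.null(best)) {
    rlang::warn("no sub-interval reaches the two-copy fraction; core is the index marker alone")
    best <- list(l = idx, r = idx, f = frac_two(idx, idx))
  }
  keep <- best$l:best$r
  mk <- shared$markers[keep, ]
  excluded <- if (is.null(dup_interval)) rep(FALSE, nrow(mk))
    else mk$pos >= dup_interval[1] & mk$pos <= dup_interval[2]
  structure(list(
    markers = dplyr::mutate(mk, excluded = excluded),
    span_start = mk$pos[1], span_end = mk$pos[nrow(mk)],
    two_copy_fraction = best$f), class = "core_haplotype")
}

#' @export
print.core_haplotype <- function(x, ...) {
  cat(sprintf("<core_haplotype> %d markers (%d excluded in-duplication), %s-%s\n",
              nrow(x$markers), sum(x$markers$excluded),
              format(x$span_start, big.mark = ","),
              format(x$span_end, big.mark = ",")))
  invisible(x)
}

#' Count core-haplotype copies per dog
#'
#' A haplotype counts as a copy when it matches the core allele at every
#' non-excluded core marker (strict matching: a missing genotype at any such
#' marker disqualifies that haplotype; a mismatch at an excluded
#' in-duplication marker is ignored).
#'
#' @inheritParams find_shared_haplotype
#' @param core A [define_core()] result (or compatible list).
#' @return Tibble `dog_id`, `copies` (0/1/2) for every dog in the array.
#' @export
count_core_copies <- function(haplotypes, core) {
  mk <- core$markers[!core$markers$excluded, ]
  if (nrow(mk) == 0L) stop_bad_arg("core has no non-excluded markers")
  H <- haplotypes[, , mk$marker_id, drop = FALSE]
  n <- dim(H)[1]
  cons <- rep(mk$allele, each = n)
  h1 <- matrix(H[, 1L, ], nrow = n)
  h2 <- matrix(H[, 2L, ], nrow = n)
  m1 <- matrix(!is.na(h1) & h1 == cons, n)
  m2 <- matrix(!is.na(h2) & h2 == cons, n)
  tibble::tibble(dog_id = dimnames(haplotypes)[[1]],
                 copies = as.integer(rowSums(m1) == nrow(mk)) +
                          as.integer(rowSums(m2) == nrow(mk)))
}

#' Haplotype-phenotype association (2x2 chi-square)
#'
#' Pearson chi-square without continuity correction on carrier (>= 1 core
#' copy) vs phenotype, at the dog level by default; `level = "allele"` tests
#' haplotype copies instead (each dog contributes two haplotypes). The odds
#' ratio uses a Haldane 0.5 correction when a cell is empty.
#'
#' @param dosages Tibble with `copies` and `phenotype` (0 brown, 1 blue).
#' @param level `"dog"` or `"allele"`.
#' @return Tibble: `level`, `statistic`, `df`, `p_value`, `odds_ratio`, and
#'   the four cell counts (`carrier_blue`, `carrier_brown`,
#'   `noncarrier_blue`, `noncarrier_brown`).
#' @export
haplotype_association <- function(dosages, level = c("dog", "allele")) {
  level <- match.arg(level)
  if (level == "dog") {
    carrier <- dosages$copies >= 1L
    pheno <- dosages$phenotype
  } else {
    carrier <- rep(c(TRUE, FALSE), c(sum(dosages$copies),
                                     sum(2L - dosages$copies)))
    pheno <- c(rep(dosages$phenotype, dosages$copies),
               rep(dosages$phenotype, 2L - dosages$copies))
  }
  tab <- matrix(c(sum(carrier & pheno == 1L), sum(carrier & pheno == 0L),
                  sum(!carrier & pheno == 1L), sum(!carrier & pheno == 0L)),
                2L, byrow = TRUE,
                dimnames = list(c("carrier", "noncarrier"),
                                c("blue", "brown")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop_bad_arg("a margin of the 2x2 table is zero; the test is undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  t2 <- if (any(tab == 0L)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble::tibble(level = level, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 odds_ratio = or,
                 carrier_blue = tab[1, 1], carrier_brown = tab[1, 2],
                 noncarrier_blue = tab[2, 1], noncarrier_brown = tab[2, 2])
}

#' Penetrance by core-haplotype copy class
#'
#' Penetrance = blue / (blue + brown) per copy class and for pooled carriers,
#' with Clopper-Pearson 95% intervals. Empty classes are reported as
#' undefined rather than zero.
#'
#' @param dosages Tibble with `copies` and `phenotype`.
#' @return Tibble: `class`, `n`, `n_blue`, `penetrance`, `ci_lo`, `ci_hi`,
#'   `defined`.
#' @export
penetrance_table <- function(dosages) {
  if (nrow(dosages) == 0L) stop_bad_arg("empty dosage table")
  one <- function(label, sel) {
    n <- sum(sel); blue <- sum(dosages$phenotype[sel] == 1L)
    if (n == 0L)
      return(tibble::tibble(class = label, n = 0L, n_blue = 0L,
                            penetrance = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, defined = FALSE))
    bt <- binom.test(blue, n)
    tibble::tibble(class = label, n = n, n_blue = blue,
                   penetrance = blue / n, ci_lo = bt$conf.int[1],
                   ci_hi = bt$conf.int[2], defined = TRUE)
  }
  dplyr::bind_rows(one("0", dosages$copies == 0L),
                   one("1", dosages$copies == 1L),
                   one("2", dosages$copies == 2L),
                   one("carrier", dosages$copies >= 1L))
}

#' Fraction of blue-eyed cases explained by the haplotype
#'
#' @param dosages Tibble with `copies` and `phenotype`.
#' @return Tibble: `n_cases`, `n_carrier_cases`, `explained_fraction`,
#'   `ci_lo`, `ci_hi` (Clopper-Pearson 95%).
#' @export
case_coverage <- function(dosages) {
  cases <- dosages[dosages$phenotype == 1L, ]
  if (nrow(cases) == 0L) stop_bad_arg("no blue-eyed cases in the table")
  k <- sum(cases$copies >= 1L)
  bt <- binom.test(k, nrow(cases))
  tibble::tibble(n_cases = nrow(cases), n_carrier_cases = k,
                 explained_fraction = k / nrow(cases),
                 ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2])
}

#' Modifier-locus test among duplication carriers
#'
#' Two-sided Fisher exact test, among carriers only, of a dominantly coded
#' modifier (>= 1 allele) against eye color; used for the melanistic-mask
#' (Em) effect, where mask-carrying duplication carriers are more often
#' brown-eyed.
#'
#' @param dosages Tibble with `copies`, `phenotype` and the modifier
#'   genotype column named by `modifier`.
#' @param modifier Column name of the modifier genotype (0/1/2).
#' @return Tibble: `p_value`, `odds_ratio` (blue odds in modifier carriers
#'   vs non-carriers), `direction` (sign of the log odds ratio; -1 means the
#'   modifier shifts carriers toward brown), cell counts, `degenerate`.
#' @export
modifier_test <- function(dosages, modifier = "mask_genotype") {
  if (!modifier %in% names(dosages))
    stop_bad_arg("no column '%s' in dosages", modifier)
  d <- dosages[dosages$copies >= 1L, ]
  if (nrow(d) == 0L) stop_bad_arg("no carriers to test")
  mod <- d[[modifier]] >= 1L
  tab <- matrix(c(sum(mod & d$phenotype == 1L), sum(mod & d$phenotype == 0L),
                  sum(!mod & d$phenotype == 1L),
                  sum(!mod & d$phenotype == 0L)), 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_,
                          direction = 0,
                          mod_blue = tab[1, 1], mod_brown = tab[1, 2],
                          nomod_blue = tab[2, 1], nomod_brown = tab[2, 2],
                          degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  t2 <- if (any(tab == 0L)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble::tibble(p_value = ft$p.value, odds_ratio = or,
                 direction = sign(log(or)),
                 mod_blue = tab[1, 1], mod_brown = tab[1, 2],
                 nomod_blue = tab[2, 1], nomod_brown = tab[2, 2],
                 degenerate = FALSE)
}
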