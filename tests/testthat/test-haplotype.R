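# shared/core haplotype extraction, copy counting, association, penetrance,
# modifier analysis

simple_markers <- function(m) {
  tibble::tibble(marker_id = sprintf("snp%02d", seq_len(m)),
                 pos = seq_len(m) * 1000L)
}

test_that("a single dog extends its own haplotype maximally through the index", {
  h1 <- matrix(c(1, 0, 1, 1, 0), 1)
  h2 <- matrix(c(1, 0, 1, 1, 0), 1)
  mk <- simple_markers(5)
  sh <- find_shared_haplotype(hap_array(h1, h2), mk, "dog01",
                              index_pos = 3000L)
  expect_identical(nrow(sh$markers), 5L)
  expect_equal(sh$markers$allele, c(1, 0, 1, 1, 0))
})

test_that("extension stops where cases stop sharing", {
  # two dogs agree only at the index marker and one marker right of it
  h1 <- rbind(c(0, 1, 1, 0), c(1, 1, 1, 1))
  h2 <- rbind(c(0, 1, 1, 0), c(1, 1, 1, 1))
  mk <- simple_markers(4)
  sh <- find_shared_haplotype(hap_array(h1, h2), mk, c("dog01", "dog02"),
                              index_pos = 2000L)
  expect_identical(sh$span_start, 2000L)
  expect_identical(sh$span_end, 3000L)
  # degenerate: nothing shared beyond the index
  h3 <- rbind(c(0, 1, 1), c(1, 1, 0))
  sh2 <- find_shared_haplotype(hap_array(h3, h3), simple_markers(3),
                               c("dog01", "dog02"), index_pos = 2000L)
  expect_identical(nrow(sh2$markers), 1L)
  expect_identical(sh2$markers$pos, 2000L)
})

test_that("dogs not homozygous at the index are reported by name", {
  h1 <- rbind(c(1, 1, 1), c(1, 0, 1))
  h2 <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_error(
    find_shared_haplotype(hap_array(h1, h2), simple_markers(3),
                          c("dog01", "dog02"), index_pos = 2000L),
    "dog02")
})

test_that("the core is the widest interval with the required two-copy fraction", {
  # 26 case homozygotes over 9 markers; all share one haplotype throughout,
  # markers 3..7 are two-copy in 24/26 dogs, the outer markers in fewer
  m <- 9
  cons <- rep(1L, m)
  h1 <- matrix(1L, 26, m)
  h2 <- matrix(1L, 26, m)
  h2[1:2, ] <- 0L; h2[1:2, 5] <- 1L          # two dogs: one copy only
  h2[3:10, 1:2] <- 0L                        # eight dogs lose the left edge
  h2[11:18, 8:9] <- 0L                       # eight dogs lose the right edge
  # keep every dog homozygous at the index marker (pos 5000)
  h2[1:2, 5] <- 1L
  mk <- simple_markers(m)
  haps <- hap_array(h1, h2)
  ids <- dimnames(haps)[[1]]
  sh <- find_shared_haplotype(haps, mk, ids, index_pos = 5000L)
  expect_identical(nrow(sh$markers), as.integer(m)) # one shared haplotype
  core <- define_core(haps, ids, sh, min_two_copy_fraction = 24 / 26)
  expect_identical(core$span_start, 3000L)
  expect_identical(core$span_end, 7000L)
  expect_equal(core$two_copy_fraction, 24 / 26)
  # a stricter fraction can only shrink the core
  core2 <- define_core(haps, ids, sh, min_two_copy_fraction = 1.0)
  expect_lte(core2$span_end - core2$span_start,
             core$span_end - core$span_start)
  # all two-copy everywhere: core equals the shared interval
  core3 <- define_core(hap_array(h1, h1), ids, sh)
  expect_identical(c(core3$span_start, core3$span_end), c(1000L, 9000L))
})

test_that("core copies are counted strictly outside the excluded markers", {
  core <- list(markers = tibble::tibble(
    marker_id = sprintf("snp%02d", 1:5),
    pos = 1:5 * 1000L,
    allele = c(1L, 0L, 1L, 1L, 0L),
    excluded = c(FALSE, FALSE, TRUE, FALSE, FALSE)))
  exact <- c(1, 0, 1, 1, 0)
  h1 <- rbind(exact, exact, exact, c(1, 1, 1, 1, 0))
  h2 <- rbind(exact, c(1, 0, 0, 1, 0), c(0, 0, 1, 1, 0), c(1, 1, 1, 1, 0))
  cc <- count_core_copies(hap_array(h1, h2), core)
  # dog1: both exact = 2; dog2: mismatch only at excluded snp03 = 2;
  # dog3: mismatch at snp01 on h2 = 1; dog4: mismatch at snp02 both = 0
  expect_identical(cc$copies, c(2L, 2L, 1L, 0L))
  # missing genotype disqualifies the haplotype
  h1na <- h1; h1na[1, 4] <- NA
  ccna <- count_core_copies(hap_array(h1na, h2), core)
  expect_identical(ccna$copies[1], 1L)
})

test_that("toggling a marker into the excluded set never lowers a copy count", {
  set.seed(31)
  for (i in 1:10) {
    m <- 8
    al <- rbinom(m, 1, 0.5)
    core <- list(markers = tibble::tibble(
      marker_id = sprintf("snp%02d", 1:m), pos = 1:m * 1000L,
      allele = al, excluded = rep(FALSE, m)))
    h1 <- matrix(rbinom(6 * m, 1, 0.5), 6)
    h2 <- matrix(rbinom(6 * m, 1, 0.5), 6)
    haps <- hap_array(h1, h2)
    before <- count_core_copies(haps, core)$copies
    core$markers$excluded[sample.int(m, 1)] <- TRUE
    after <- count_core_copies(haps, core)$copies
    expect_true(all(after >= before))
  }
})

test_that("core recovery finds the planted causal haplotype", {
  ok <- vapply(1:10, function(s) {
    co <- simulate_cohort(population_config(n_dogs = 800, n_markers = 200,
                                            n_background_markers = 0,
                                            seed = 300 + s))
    mk <- co$markers
    idx_pos <- mk$pos[mk$core & !mk$in_dup][1]
    idx <- match(idx_pos, mk$pos)
    al <- co$core_alleles[mk$marker_id[idx]]
    cases <- co$dogs$dog_id[co$dogs$phenotype == 1 & co$dogs$dup_copies == 2 &
                              co$haplotypes[, 1, idx] == al &
                              co$haplotypes[, 2, idx] == al]
    if (length(cases) < 2) return(NA)
    sh <- find_shared_haplotype(co$haplotypes, mk, cases, idx_pos)
    core <- define_core(co$haplotypes, cases, sh,
                        dup_interval = c(co$dup_start, co$dup_end))
    causal <- mk$pos[mk$core]
    all(causal >= core$span_start & causal <= core$span_end)
  }, logical(1))
  ok <- ok[!is.na(ok)]
  expect_gte(mean(ok), 0.95)
})

test_that("haplotype association matches the Pearson chi-square by hand", {
  # proportional table: no association
  prop <- dosages_from_counts(20, 10, 40, 20)
  out <- haplotype_association(prop)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  # published discovery counts: 81/108 blue carriers, 46/2661 brown carriers
  disc <- dosages_from_counts(81, 27, 46, 2615)
  out2 <- haplotype_association(disc)
  expect_equal(out2$statistic, 1273.278, tolerance = 1e-3)
  expect_lt(out2$p_value, 1e-270)
  expect_gt(out2$p_value, 1e-290)
  # zero margin is an error
  expect_error(haplotype_association(dosages_from_counts(0, 0, 5, 5)),
               "margin")
})

test_that("chi-square equals the direct-summation oracle on random tables", {
  set.seed(33)
  for (i in 1:50) {
    cells <- rbinom(4, 30, 0.5) + 1L
    dos <- dosages_from_counts(cells[1], cells[2], cells[3], cells[4])
    got <- haplotype_association(dos)
    tab <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2, byrow = TRUE)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - exp_tab)^2 / exp_tab),
                 tolerance = 1e-10)
  }
})

test_that("dominant coding: collapsing dosage 2 to 1 leaves the test unchanged", {
  set.seed(34)
  dos <- tibble::tibble(copies = sample(0:2, 400, replace = TRUE,
                                        prob = c(0.8, 0.15, 0.05)),
                        phenotype = rbinom(400, 1, 0.3))
  collapsed <- dplyr::mutate(dos, copies = pmin(copies, 1L))
  expect_identical(haplotype_association(dos),
                   haplotype_association(collapsed))
})

test_that("allele-level association uses one row per haplotype", {
  dos <- tibble::tibble(copies = c(2L, 1L, 0L), phenotype = c(1L, 1L, 0L))
  out <- haplotype_association(dos, level = "allele")
  expect_identical(out$carrier_blue + out$carrier_brown, 3L)
  expect_identical(out$noncarrier_blue + out$noncarrier_brown, 3L)
})

test_that("penetrance estimates carry exact fractions and Clopper-Pearson CIs", {
  dos <- tibble::tibble(copies = rep(c(1L, 0L), c(10, 5)),
                        phenotype = rep(c(1L, 0L, 0L), c(8, 2, 5)))
  pen <- penetrance_table(dos)
  carrier <- pen[pen$class == "carrier", ]
  expect_equal(carrier$penetrance, 0.8)
  ci <- binom.test(8, 10)$conf.int
  expect_equal(c(carrier$ci_lo, carrier$ci_hi), as.numeric(ci))
  # validation-panel photographed carriers: 45 of 46 blue or heterochromic
  val <- tibble::tibble(copies = 1L, phenotype = rep(c(1L, 0L), c(45, 1)))
  expect_equal(penetrance_table(val)$penetrance[4], 45 / 46,
               tolerance = 1e-12)
  # an empty class is undefined, not zero
  expect_false(pen$defined[pen$class == "2"])
  expect_true(is.na(pen$penetrance[pen$class == "2"]))
})

test_that("the haplotype explains 75% of the published blue-eyed cases", {
  disc <- dosages_from_counts(81, 27, 46, 2615)
  cov <- case_coverage(disc)
  expect_identical(cov$n_cases, 108L)
  expect_equal(cov$explained_fraction, 0.75)
})

test_that("the modifier Fisher test matches the hypergeometric closed form", {
  # table [[10,0],[0,10]] has two-sided p = 2 / C(20,10)
  dos <- tibble::tibble(copies = 1L,
                        phenotype = rep(c(1L, 0L), each = 10),
                        mask_genotype = rep(c(1L, 0L), each = 10))
  out <- modifier_test(dos)
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # independence: p = 1
  ind <- tibble::tibble(copies = 1L,
                        phenotype = rep(c(1L, 0L, 1L, 0L), each = 5),
                        mask_genotype = rep(c(1L, 1L, 0L, 0L), each = 5))
  expect_equal(modifier_test(ind)$p_value, 1)
  # zero margin: degenerate flag
  deg <- tibble::tibble(copies = 1L, phenotype = 1L,
                        mask_genotype = rep(c(0L, 1L), 5))
  out_deg <- modifier_test(deg)
  expect_true(out_deg$degenerate)
  expect_identical(out_deg$p_value, 1)
})

test_that("the mask effect is detected in most simulated carrier panels", {
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(population_config(n_dogs = 5000, n_markers = 50,
                                            n_background_markers = 0,
                                            seed = 400 + s))
    dos <- dplyr::mutate(co$dogs, copies = dup_copies)
    out <- modifier_test(dos)
    out$p_value < 0.05 && out$direction == -1
  }, logical(1))
  expect_gte(sum(hits), 8)
})
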