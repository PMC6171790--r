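# hard filters, carrier-exclusive variants, consequence classification

clean_snp <- function(pos = 100L, ...) {
  defaults <- list(variant_id = paste0("v", pos), pos = pos, ref = "A",
                   alt = "G", depth = 10, fs = 5, readpos_z = 0, mq_rms = 60,
                   mqrank_z = 0)
  tibble::as_tibble(utils::modifyList(defaults, list(...)))
}

test_that("hard filters fire as strict per-annotation rejection rules", {
  keep <- clean_snp(1)
  expect_identical(nrow(hard_filter(keep)$variants), 1L)
  # boundary: FS of exactly 60 retained, 61 rejected
  expect_identical(nrow(hard_filter(clean_snp(2, fs = 60))$variants), 1L)
  rej <- hard_filter(clean_snp(3, fs = 61))
  expect_identical(nrow(rej$variants), 0L)
  expect_match(rej$rejected$filter, "strand_bias")
  # missing annotation means the rule is skipped, and counted
  na_fs <- hard_filter(clean_snp(4, fs = NA_real_))
  expect_identical(nrow(na_fs$variants), 1L)
  expect_identical(
    na_fs$counts$n_not_applied[na_fs$counts$rule == "strand_bias"], 1L)
  # indels use their own thresholds and skip the mapping-quality rules
  indel <- clean_snp(5, ref = "AT", alt = "A", fs = 100, readpos_z = -15,
                     mq_rms = 10, mqrank_z = -20)
  expect_identical(nrow(hard_filter(indel)$variants), 1L)
  indel_bad <- clean_snp(6, ref = "AT", alt = "A", fs = 201)
  expect_identical(nrow(hard_filter(indel_bad)$variants), 0L)
})

test_that("a hand-annotated 12-variant panel keeps exactly the expected 7", {
  v <- dplyr::bind_rows(
    clean_snp(1),                                   # pass
    clean_snp(2, depth = 1),                        # low depth
    clean_snp(3, fs = 75),                          # strand bias
    clean_snp(4, readpos_z = -9),                   # read position
    clean_snp(5, mq_rms = 35),                      # mapping quality
    clean_snp(6, mqrank_z = -13),                   # MQ rank sum
    clean_snp(7, fs = 59.9),                        # pass (under bound)
    clean_snp(8, ref = "A", alt = "AGG", fs = 150), # indel: pass
    clean_snp(9, ref = "ATT", alt = "A",
              readpos_z = -19),                     # indel: pass (> -20)
    clean_snp(10, ref = "C", alt = "CT",
              mq_rms = 10),                         # indel: MQ not applied
    clean_snp(11, readpos_z = -7.9),                # pass (over bound)
    clean_snp(12, depth = 2))                       # pass (depth not < 2)
  out <- hard_filter(v)
  expect_identical(nrow(out$variants), 7L)
  expect_setequal(out$variants$variant_id,
                  paste0("v", c(1, 7, 8, 9, 10, 11, 12)))
  expect_identical(nrow(out$variants) + nrow(out$rejected), 12L)
  expect_identical(sum(out$counts$n_rejected >= 1), 5L)
})

test_that("tightening any threshold never enlarges the retained set", {
  set.seed(41)
  v <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:200), pos = 1:200,
    ref = sample(c("A", "AT"), 200, replace = TRUE), alt = "G",
    depth = rpois(200, 8), fs = rexp(200, 1 / 40),
    readpos_z = rnorm(200, 0, 6), mq_rms = rnorm(200, 45, 8),
    mqrank_z = rnorm(200, 0, 7))
  base <- hard_filter(v)$variants$variant_id
  tighter <- list(
    variant_filter_config(min_depth = 5),
    variant_filter_config(max_fs_snp = 30),
    variant_filter_config(max_fs_indel = 100),
    variant_filter_config(min_readpos_z_snp = -4),
    variant_filter_config(min_mq_rms_snp = 50),
    variant_filter_config(min_mqrank_z_snp = -5))
  for (cfg in tighter) {
    kept <- hard_filter(v, cfg)$variants$variant_id
    expect_true(all(kept %in% base))
  }
})

test_that("carrier-exclusive variants match the set-operation oracle", {
  set.seed(42)
  for (i in 1:20) {
    n_var <- sample(5:20, 1)
    n_car <- sample(1:3, 1)
    n_non <- sample(1:3, 1)
    samples <- sprintf("s%d", seq_len(n_car + n_non))
    geno <- matrix(sample(c(0:2, NA), n_var * length(samples), replace = TRUE,
                          prob = c(0.5, 0.2, 0.1, 0.2)),
                   n_var, length(samples),
                   dimnames = list(sprintf("v%02d", seq_len(n_var)), samples))
    carriers <- samples[seq_len(n_car)]
    noncarr <- setdiff(samples, carriers)
    got <- carrier_exclusive(geno, carriers, noncarr)
    oracle <- rownames(geno)[vapply(seq_len(n_var), function(r) {
      g <- geno[r, ]
      all(!is.na(g[carriers]) & g[carriers] >= 1) &&
        all(!is.na(g[noncarr]) & g[noncarr] == 0)
    }, logical(1))]
    expect_identical(got, oracle)
  }
  expect_error(carrier_exclusive(matrix(1, 1, 1,
                                        dimnames = list("v", "s")),
                                 character(), "s"), "empty carrier")
})

test_that("carrier-exclusive examples behave as stated", {
  geno <- matrix(0L, 2, 9,
                 dimnames = list(c("vA", "vB"), sprintf("s%d", 1:9)))
  carriers <- sprintf("s%d", 1:4)
  noncarr <- sprintf("s%d", 5:9)
  geno["vA", carriers] <- 1L
  geno["vB", carriers] <- 1L
  geno["vB", "s5"] <- 1L          # leaks into one non-carrier
  expect_identical(carrier_exclusive(geno, carriers, noncarr), "vA")
})

test_that("consequences are classified by containment with codon translation", {
  # forward-strand gene: exon 101-400, CDS 151-300 (in frame from 151)
  seq <- paste(rep("ACGT", 150), collapse = "")
  fwd <- gene_model("geneF", "+",
                    exons = data.frame(start = 101, end = 400),
                    cds = data.frame(start = 151, end = 300),
                    seq = seq, seq_start = 1L)
  # GCT -> GCC is synonymous (Ala): build explicit codon at 151..153
  seq2 <- paste0(strrep("A", 150), "GCT", strrep("A", 147))
  fwd2 <- gene_model("geneF", "+", exons = data.frame(start = 101, end = 400),
                     cds = data.frame(start = 151, end = 300),
                     seq = seq2, seq_start = 1L)
  syn <- classify_consequence(list(pos = 153, ref = "T", alt = "C"), fwd2)
  expect_identical(syn$class, "CDS")
  expect_true(syn$synonymous)
  nonsyn <- classify_consequence(list(pos = 152, ref = "C", alt = "A"), fwd2)
  expect_false(nonsyn$synonymous)   # GCT (Ala) -> GAT (Asp)
  # insertion in the 3' UTR of a forward gene (exonic, right of the CDS)
  utr3 <- classify_consequence(list(pos = 350, ref = "A", alt = "AGG"), fwd)
  expect_identical(utr3$class, "UTR3")
  # exonic left of the CDS on the forward strand is 5' UTR
  expect_identical(
    classify_consequence(list(pos = 120, ref = "A", alt = "G"), fwd)$class,
    "UTR5")
  expect_identical(
    classify_consequence(list(pos = 140, ref = "A", alt = "G"),
                         gene_model("geneR", "-",
                                    exons = data.frame(start = 101, end = 400),
                                    cds = data.frame(start = 151, end = 300),
                                    seq = seq, seq_start = 1L))$class,
    "UTR3")
  # intronic and intergenic positions
  two_exon <- gene_model("geneI", "+",
                         exons = data.frame(start = c(101, 301),
                                            end = c(200, 400)),
                         cds = data.frame(start = c(151, 301),
                                          end = c(200, 350)),
                         seq = seq, seq_start = 1L)
  expect_identical(
    classify_consequence(list(pos = 250, ref = "A", alt = "G"),
                         two_exon)$class, "intron")
  expect_identical(
    classify_consequence(list(pos = 500, ref = "A", alt = "G"), fwd)$class,
    "intergenic")
  # an allele spanning the CDS edge is CDS with a boundary flag
  bnd <- classify_consequence(list(pos = 299, ref = "AAA", alt = "A"), fwd)
  expect_identical(bnd$class, "CDS")
  expect_true(bnd$boundary)
})

test_that("reverse-strand classification equals the complemented forward construction", {
  # forward gene: transcript codons ATG GCC ... starting at CDS 151
  fseq <- paste0(strrep("A", 150), "ATGGCC", strrep("A", 144))
  fwd <- gene_model("gF", "+", exons = data.frame(start = 101, end = 400),
                    cds = data.frame(start = 151, end = 300),
                    seq = fseq, seq_start = 1L)
  # minus-strand gene encoding the same transcript: the CDS is read from
  # genomic 300 downward with complementation, so ATG GCC needs
  # complemented bases at 300..295
  rs <- rep("A", 300)
  rs[c(300, 299, 298)] <- c("T", "A", "C")   # -> ATG
  rs[c(297, 296, 295)] <- c("C", "G", "G")   # -> GCC
  rev_model <- gene_model("gR", "-",
                          exons = data.frame(start = 101, end = 400),
                          cds = data.frame(start = 151, end = 300),
                          seq = paste(rs, collapse = ""), seq_start = 1L)
  # third base of codon 1 mutated in both encodings: ATG -> ATA (Met->Ile)
  f_non <- classify_consequence(list(pos = 153, ref = "G", alt = "A"), fwd)
  r_non <- classify_consequence(list(pos = 298, ref = "C", alt = "T"),
                                rev_model)
  expect_identical(f_non$class, "CDS")
  expect_identical(r_non$class, "CDS")
  expect_false(f_non$synonymous)
  expect_identical(f_non$synonymous, r_non$synonymous)
  # third base of codon 2 mutated: GCC -> GCA (Ala->Ala), synonymous
  f_syn <- classify_consequence(list(pos = 156, ref = "C", alt = "A"), fwd)
  r_syn <- classify_consequence(list(pos = 295, ref = "G", alt = "T"),
                                rev_model)
  expect_true(f_syn$synonymous)
  expect_identical(f_syn$synonymous, r_syn$synonymous)
})
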