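#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates a breed-structured diploid cohort genotyped over a
#' single ~2-Mb chromosome-18-like region: haplotypes are assembled by
#' block-copying from breed-specific founder pools (which creates linkage
#' disequilibrium and tag-SNP structure without coalescent machinery), a
#' causal duplication-bearing haplotype segregates in one breed, and a binary
#' blue-eye phenotype is drawn with dominant but incomplete penetrance,
#' a merle-like phenocopy locus, and a melanistic-mask (Em) modifier that
#' reduces penetrance in duplication carriers.
#'
#' @param n_dogs Number of dogs.
#' @param n_markers Number of array markers in the region (>= 50). Six of
#'   them are always placed at the canonical in-duplication positions.
#' @param n_breeds Number of breeds; dogs are assigned uniformly at random.
#' @param breed_fst Drift parameter in `[0,1)` for breed allele-frequency
#'   divergence (Balding-Nichols model).
#' @param dup_haplotype_freq Population frequency of the duplication-bearing
#'   haplotype. The default is tuned so the expected carrier (>= 1 copy)
#'   fraction is 10%. The haplotype segregates only in breed 1, so its
#'   within-breed frequency is `dup_haplotype_freq * n_breeds`; configurations
#'   where that exceeds 1 are rejected.
#' @param penetrance_carrier P(blue | >= 1 duplication copy), before the mask
#'   modifier.
#' @param penetrance_noncarrier P(blue | 0 copies): background phenocopies.
#' @param merle_freq Allele frequency of the merle-like confounder locus
#'   (unlinked to the region).
#' @param merle_blue_prob P(blue) for a non-carrier with >= 1 merle allele
#'   (phenocopy probability; applied as `max(penetrance_noncarrier, .)`).
#' @param mask_freq Allele frequency of the Em (melanistic mask) modifier.
#' @param mask_brown_boost Multiplicative reduction of carrier penetrance in
#'   Em carriers: masked carriers have penetrance
#'   `penetrance_carrier * (1 - mask_brown_boost)`.
#' @param ld_block_length Markers per haplotype copying block.
#' @param n_founders Founder haplotypes per breed pool.
#' @param n_background_markers Unlinked genome-background markers drawn under
#'   the same breed structure; they stand in for the rest of the genome when
#'   building the relatedness matrix (the focal region contributes almost
#'   nothing to a genome-wide GRM, so using only background markers mirrors
#'   the genome-wide / leave-one-chromosome-out practice).
#' @param region_start,region_end 1-based bp span of the simulated region.
#' @param dup_start,dup_end 1-based inclusive bp interval of the duplication
#'   (default the 98,607-bp interval 44,791,417..44,890,023).
#' @param include_partial_dog If `TRUE`, the last dog is forced to be a
#'   heterozygous carrier whose duplication covers only a prefix of the
#'   interval (a partial-duplication outlier for intensity analysis).
#' @param seed Integer master seed; the generator is fully reproducible.
#'
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_dogs = 3180L,
                              n_markers = 500L,
                              n_breeds = 5L,
                              breed_fst = 0.1,
                              dup_haplotype_freq = tune_dup_freq(0.10, n_breeds),
                              penetrance_carrier = 0.65,
                              penetrance_noncarrier = 0.01,
                              merle_freq = 0.05,
                              merle_blue_prob = 0.25,
                              mask_freq = 0.20,
                              mask_brown_boost = 0.5,
                              ld_block_length = 25L,
                              n_founders = 20L,
                              n_background_markers = 400L,
                              region_start = 44000000L,
                              region_end = 46000000L,
                              dup_start = 44791417L,
                              dup_end = 44890023L,
                              include_partial_dog = FALSE,
                              seed = 1L) {
  n_dogs <- check_count(n_dogs, "n_dogs")
  n_markers <- check_count(n_markers, "n_markers", min = 50L)
  n_breeds <- check_count(n_breeds, "n_breeds")
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_background_markers <- check_count(n_background_markers,
                                      "n_background_markers", min = 0L)
  ld_block_length <- check_count(ld_block_length, "ld_block_length")
  check_fraction(breed_fst, "breed_fst", allow_one = FALSE)
  for (nm in c("dup_haplotype_freq", "penetrance_carrier",
               "penetrance_noncarrier", "merle_freq", "merle_blue_prob",
               "mask_freq", "mask_brown_boost"))
    check_fraction(get(nm), nm)
  if (penetrance_carrier < penetrance_noncarrier)
    stop_bad_arg("penetrance_carrier (%g) must be >= penetrance_noncarrier (%g)",
                 penetrance_carrier, penetrance_noncarrier)
  if (!(region_start <= dup_start && dup_start < dup_end && dup_end <= region_end))
    stop_bad_arg("duplication interval must satisfy region_start <= dup_start < dup_end <= region_end")
  q_within <- dup_haplotype_freq * n_breeds
  if (q_within > 1)
    stop_bad_arg(paste0(
      "causal haplotype cannot reach frequency %g: it segregates in 1 of %d ",
      "breeds, which would require within-breed frequency %g > 1"),
      dup_haplotype_freq, n_breeds, q_within)
  structure(list(
    n_dogs = n_dogs, n_markers = n_markers, n_breeds = n_breeds,
    breed_fst = breed_fst, dup_haplotype_freq = dup_haplotype_freq,
    penetrance_carrier = penetrance_carrier,
    penetrance_noncarrier = penetrance_noncarrier,
    merle_freq = merle_freq, merle_blue_prob = merle_blue_prob,
    mask_freq = mask_freq, mask_brown_boost = mask_brown_boost,
    ld_block_length = ld_block_length, n_founders = n_founders,
    n_background_markers = n_background_markers,
    region_start = as.integer(region_start), region_end = as.integer(region_end),
    dup_start = as.integer(dup_start), dup_end = as.integer(dup_end),
    include_partial_dog = isTRUE(include_partial_dog),
    seed = as.integer(seed)), class = "population_config")
}

#' Duplication-haplotype frequency giving a target carrier fraction
#'
#' With dogs assigned uniformly to `n_breeds` breeds and the haplotype
#' segregating in one breed at within-breed frequency q under random mating,
#' the expected carrier fraction is `(2q - q^2) / n_breeds`. This inverts
#' that relation.
#'
#' @param carrier_fraction Target P(>= 1 copy), e.g. 0.10.
#' @param n_breeds Number of breeds in the cohort.
#' @return Population haplotype frequency.
#' @export
tune_dup_freq <- function(carrier_fraction = 0.10, n_breeds = 5L) {
  check_fraction(carrier_fraction, "carrier_fraction")
  if (carrier_fraction * n_breeds >= 1)
    stop_bad_arg("carrier fraction %g unreachable with %d breeds",
                 carrier_fraction, n_breeds)
  q <- 1 - sqrt(1 - carrier_fraction * n_breeds)
  q / n_breeds
}

# Marker positions: the six canonical in-duplication array positions plus
# n - 6 markers evenly spread over the region outside the duplication.
marker_positions_for <- function(config) {
  in_dup_pos <- c(44825760L, 44838433L, 44849276L, 44855038L, 44858831L,
                  44876627L)
  in_dup_pos <- in_dup_pos[in_dup_pos >= config$dup_start &
                           in_dup_pos <= config$dup_end]
  if (length(in_dup_pos) == 0L) {
    # non-default duplication interval: place 6 markers evenly inside it
    in_dup_pos <- as.integer(round(seq(config$dup_start, config$dup_end,
                                       length.out = 8L)[2:7]))
  }
  n_out <- config$n_markers - length(in_dup_pos)
  len1 <- config$dup_start - config$region_start        # bases before dup
  len2 <- config$region_end - config$dup_end            # bases after dup
  u <- round(seq(1, len1 + len2, length.out = n_out))
  pos_out <- ifelse(u <= len1, config$region_start + u - 1L,
                    config$dup_end + (u - len1))
  pos <- sort(unique(c(as.integer(pos_out), in_dup_pos)))
  if (length(pos) != config$n_markers)
    stop_bad_arg("could not place %d distinct markers in the region",
                 config$n_markers)
  pos
}

#' Simulate a breed-structured cohort with a causal duplication haplotype
#'
#' Draws founder haplotype pools per breed under a Balding-Nichols
#' allele-frequency model, assembles each dog's two haplotypes by copying
#' blocks of `ld_block_length` markers from random founders of its breed,
#' embeds a duplication-bearing founder haplotype in breed 1 (so nearby
#' markers tag it imperfectly through shared founder alleles), and draws the
#' binary eye-color phenotype from the configured penetrance model.
#'
#' @param config A [population_config()].
#' @return An object of class `synthetic_cohort`: a list with
#'   `dogs` (tibble: `dog_id`, `breed_label`, `dup_copies`, `merle_genotype`,
#'   `mask_genotype`, `phenotype`), `markers` (tibble: `marker_id`, `pos`,
#'   `in_dup`, `core`), `genotypes` (dogs x markers 0/1/2 matrix),
#'   `haplotypes` (dogs x 2 x markers 0/1 array), `core_alleles` (alleles of
#'   the causal core at core markers), the duplication interval, and the
#'   config. The genotype matrix always equals the sum of the two phased
#'   haplotypes.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "population_config"))
  pos <- marker_positions_for(config)
  m <- config$n_markers
  n <- config$n_dogs
  B <- config$n_breeds
  H <- config$n_founders
  in_dup <- pos >= config$dup_start & pos <= config$dup_end

  blocks <- ceiling(seq_len(m) / config$ld_block_length)
  n_blocks <- max(blocks)
  causal_blocks <- unique(blocks[in_dup])
  core_idx <- which(blocks %in% causal_blocks)

  with_seed(derive_seed(config$seed, "cohort"), {
    p_anc <- runif(m, 0.1, 0.9)
    founders <- vector("list", B)
    for (b in seq_len(B)) {
      if (config$breed_fst > 0) {
        fst <- config$breed_fst
        p_b <- qbeta(runif(m), p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst)
      } else p_b <- p_anc
      founders[[b]] <- matrix(rbinom(H * m, 1L, rep(p_b, each = H)), nrow = H)
    }
    # breed-1 founder 1 is the duplication haplotype; make its core allele
    # pattern unique among all founders so pattern-matching equals identity
    core_pat <- founders[[1]][1L, core_idx]
    check_cols <- core_idx[!in_dup[core_idx]]
    for (b in seq_len(B)) {
      rows <- if (b == 1L) 2:H else seq_len(H)
      for (h in rows) {
        if (all(founders[[b]][h, check_cols] == founders[[1]][1L, check_cols]))
          founders[[b]][h, check_cols[1L]] <- 1L - founders[[b]][h, check_cols[1L]]
      }
    }

    breed <- sample.int(B, n, replace = TRUE)
    q_within <- config$dup_haplotype_freq * B

    hap <- array(0L, dim = c(n, 2L, m))
    dup_hap <- matrix(FALSE, n, 2L)
    for (k in 1:2) {
      # founder choice per dog per block
      choice <- matrix(sample.int(H, n * n_blocks, replace = TRUE), n, n_blocks)
      is_dup <- breed == 1L & runif(n) < q_within
      dup_hap[, k] <- is_dup
      # the causal blocks are one IBD segment: one founder choice for all
      seg_founder <- ifelse(is_dup, 1L,
                            1L + sample.int(H - 1L, n, replace = TRUE))
      choice[, causal_blocks] <- seg_founder
      for (b in seq_len(B)) {
        dogs_b <- which(breed == b)
        if (!length(dogs_b)) next
        fo <- founders[[b]]
        fidx <- choice[dogs_b, , drop = FALSE][, blocks, drop = FALSE]
        hap[dogs_b, k, ] <- fo[cbind(as.vector(fidx),
                                     rep(seq_len(m), each = length(dogs_b)))]
      }
    }

    partial_dog <- NA_character_
    if (config$include_partial_dog) {
      # force the last dog to carry one duplication haplotype (its intensity
      # signature covers only a prefix of the interval; see
      # simulate_intensities)
      breed[n] <- 1L
      hap[n, 1L, core_idx] <- founders[[1]][1L, core_idx]
      dup_hap[n, 1L] <- TRUE
      partial_dog <- sprintf("dog%04d", n)
    }

    dup_copies <- rowSums(dup_hap)
    merle <- rbinom(n, 2L, config$merle_freq)
    mask <- rbinom(n, 2L, config$mask_freq)

    # unlinked background markers (one per locus, no LD): breed-specific
    # frequencies under the same drift model, used for the relatedness matrix
    nb <- config$n_background_markers
    background <- NULL
    if (nb > 0L) {
      pb_anc <- runif(nb, 0.1, 0.9)
      pb <- matrix(0, B, nb)
      for (b in seq_len(B)) {
        pb[b, ] <- if (config$breed_fst > 0) {
          fst <- config$breed_fst
          qbeta(runif(nb), pb_anc * (1 - fst) / fst,
                (1 - pb_anc) * (1 - fst) / fst)
        } else pb_anc
      }
      background <- matrix(rbinom(n * nb, 2L, pb[breed, ]), n, nb,
                           dimnames = list(sprintf("dog%04d", seq_len(n)),
                                           sprintf("bg%04d", seq_len(nb))))
    }
  })

  with_seed(derive_seed(config$seed, "phenotype"), {
    p_blue <- ifelse(
      dup_copies >= 1L,
      config$penetrance_carrier *
        ifelse(mask >= 1L, 1 - config$mask_brown_boost, 1),
      ifelse(merle >= 1L,
             pmax(config$penetrance_noncarrier, config$merle_blue_prob),
             config$penetrance_noncarrier))
    phenotype <- rbinom(config$n_dogs, 1L, p_blue)
  })

  geno <- hap[, 1L, ] + hap[, 2L, ]
  ids <- sprintf("dog%04d", seq_len(n))
  mids <- sprintf("snp%04d", seq_len(m))
  dimnames(geno) <- list(ids, mids)
  dimnames(hap) <- list(ids, c("h1", "h2"), mids)

  structure(list(
    dogs = tibble::tibble(
      dog_id = ids,
      breed_label = sprintf("breed%d", breed),
      dup_copies = as.integer(dup_copies),
      merle_genotype = merle, mask_genotype = mask,
      phenotype = as.integer(phenotype)),
    markers = tibble::tibble(
      marker_id = mids, pos = pos, in_dup = in_dup,
      core = seq_len(m) %in% core_idx),
    genotypes = geno,
    haplotypes = hap,
    core_alleles = setNames(founders[[1]][1L, core_idx], mids[core_idx]),
    background = background,
    dup_start = config$dup_start, dup_end = config$dup_end,
    partial_dog = partial_dog,
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d dogs x %d markers (%d in-duplication), %d breeds\n",
    nrow(x$dogs), nrow(x$markers), sum(x$markers$in_dup),
    x$config$n_breeds))
  cat(sprintf("  duplication: %s-%s (%s bp); carriers: %d (%.1f%%); blue-eyed: %d\n",
              format(x$dup_start, big.mark = ","),
              format(x$dup_end, big.mark = ","),
              format(x$dup_end - x$dup_start + 1L, big.mark = ","),
              sum(x$dogs$dup_copies >= 1),
              100 * mean(x$dogs$dup_copies >= 1), sum(x$dogs$phenotype)))
  invisible(x)
}

#' @export
tidy.synthetic_cohort <- function(x, ...) x$dogs
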