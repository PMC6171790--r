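# End-to-end orchestration: validated YAML config, staged execution
# (simulate -> gwas -> svdepth -> intensity -> haplotype -> variantqc), each
# stage writing its outputs before the next starts, and a machine-readable
# report with provenance.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "irisdup_out",
    stages = c("simulate", "gwas", "svdepth", "intensity", "haplotype",
               "variantqc"),
    cohort = list(),       # population_config() overrides
    reads = list(),        # read_sim_config() overrides
    read_copies = 1L,
    gwas = list(),         # gwas_config() overrides
    intensity = list(het_threshold = 0.15, hom_threshold = 0.5,
                     flank_window_bp = 1e6),
    sv = list(window_bp = 10000L, step_bp = 2500L, min_support = 3L,
              max_span_slop_bp = 10000L, min_ratio = 1.4),
    variants = list(),     # variant_filter_config() overrides
    n_variants = 40L,
    paths = list(genotypes = NULL, phenotypes = NULL, intensities = NULL,
                 alignments = NULL))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in every default, rejects
#' unknown keys, and aggregates all validation errors into one message.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A list of class `pipeline_config` with all defaults materialized.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bad_arg("config file '%s' not found", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown config keys: %s",
                                paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  cfg$stages <- as.character(cfg$stages)
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage))
    errors <- c(errors, sprintf("unknown stages: %s",
                                paste(bad_stage, collapse = ", ")))
  for (sect in c("cohort", "reads", "gwas", "variants")) {
    ctor <- switch(sect, cohort = population_config,
                   reads = read_sim_config, gwas = gwas_config,
                   variants = variant_filter_config)
    bad <- setdiff(names(cfg[[sect]]), names(formals(ctor)))
    if (length(bad))
      errors <- c(errors, sprintf("unknown %s keys: %s", sect,
                                  paste(bad, collapse = ", ")))
  }
  built <- NULL
  if (!length(errors)) {
    built <- tryCatch(list(
      cohort = do.call(population_config,
                       c(cfg$cohort[setdiff(names(cfg$cohort), "seed")],
                         list(seed = cfg$seed))),
      reads = do.call(read_sim_config,
                      c(cfg$reads[setdiff(names(cfg$reads), "seed")],
                        list(seed = cfg$seed))),
      gwas = do.call(gwas_config, cfg$gwas),
      variants = do.call(variant_filter_config, cfg$variants)),
      error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  }
  needs_sim <- !"simulate" %in% cfg$stages
  if (needs_sim && "gwas" %in% cfg$stages &&
      (is.null(cfg$paths$genotypes) || is.null(cfg$paths$phenotypes)))
    errors <- c(errors,
                "gwas enabled without the simulate stage: paths$genotypes and paths$phenotypes are required")
  for (p in unlist(cfg$paths))
    if (!is.null(p) && !file.exists(p))
      errors <- c(errors, sprintf("input file '%s' does not exist", p))
  if (length(errors))
    stop_bad_arg("invalid pipeline config:\n- %s",
                 paste(errors, collapse = "\n- "))
  cfg$built <- built
  structure(cfg, class = "pipeline_config")
}

# deterministic toy resequencing panel: a handful of sequenced dogs with
# annotated variants, a few of them exclusive to duplication carriers
simulate_variant_panel <- function(cohort, n_variants = 40L, seed = 1L) {
  dogs <- cohort$dogs
  carriers <- head(dogs$dog_id[dogs$dup_copies >= 1L], 4L)
  noncarr <- head(dogs$dog_id[dogs$dup_copies == 0L], 5L)
  samples <- c(carriers, noncarr)
  with_seed(derive_seed(seed, "variants"), {
    pos <- sort(sample.int(1000000L, n_variants)) + 44500000L
    type <- sample(c("SNP", "indel"), n_variants, replace = TRUE,
                   prob = c(0.7, 0.3))
    ref <- ifelse(type == "SNP", "A", "AT")
    alt <- "G"
    v <- tibble::tibble(
      variant_id = sprintf("var%03d", seq_len(n_variants)),
      pos = pos, ref = ref, alt = alt, type = type,
      depth = rbinom(n_variants, 60L, 0.4),
      fs = round(stats::rexp(n_variants, 1 / 12), 2),
      readpos_z = round(rnorm(n_variants, 0, 3), 2),
      mq_rms = round(rnorm(n_variants, 55, 6), 1),
      mqrank_z = round(rnorm(n_variants, 0, 3), 2))
    geno <- matrix(rbinom(n_variants * length(samples), 2L, 0.25),
                   n_variants, length(samples),
                   dimnames = list(v$variant_id, samples))
    exclusive <- sample.int(n_variants, 5L)
    geno[exclusive, carriers] <- 1L +
      rbinom(length(exclusive) * length(carriers), 1L, 0.5)
    geno[exclusive, noncarr] <- 0L
    list(variants = v, genotypes = geno, carriers = carriers,
         noncarriers = noncarr, truth_exclusive = sort(v$variant_id[exclusive]))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order; every stage writes its outputs into
#' `out_dir` before the next starts, so a failure leaves the completed-stage
#' manifest intact. With the `simulate` stage enabled the pipeline is fully
#' self-contained and deterministic given the seed.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return A list of class `analysis_report`: one entry per completed stage
#'   plus `provenance` (config hash, seed, package version). Also written to
#'   `out_dir/report.json` and summarized in `out_dir/report.md`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  save_report <- function() {
    prov <- list(
      config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                        "built")]),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("irisdup")))
    out <- c(report, list(provenance = prov))
    jsonlite::write_json(out, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    out
  }
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      save_report()
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "irisdup_stage_error")
    })
    report[[name]] <<- res
    save_report()
    invisible(res)
  }

  env <- new.env()

  run_stage("simulate", function() {
    env$cohort <- simulate_cohort(config$built$cohort)
    env$intensities <- simulate_intensities(env$cohort,
                                            seed = config$seed)
    env$alignments <- simulate_read_alignments(config$built$reads,
                                               copies = config$read_copies)
    manifest <- write_fixtures(env$cohort, file.path(config$out_dir, "sim"),
                               intensities = env$intensities,
                               alignments = env$alignments,
                               read_config = config$built$reads)
    list(n_dogs = nrow(env$cohort$dogs),
         n_markers = nrow(env$cohort$markers),
         carrier_fraction = mean(env$cohort$dogs$dup_copies >= 1L),
         n_blue = sum(env$cohort$dogs$phenotype),
         files = manifest$file)
  })

  if (!"simulate" %in% config$stages && !is.null(config$paths$genotypes)) {
    gv <- read_genotypes_vcf(config$paths$genotypes)
    ph <- readr::read_tsv(config$paths$phenotypes, show_col_types = FALSE)
    env$genotypes <- gv$genotypes
    env$phenotype <- ph$phenotype[match(rownames(gv$genotypes), ph$dog_id)]
    env$markers <- gv$markers
  }

  run_stage("gwas", function() {
    if (!is.null(env$cohort)) {
      geno <- env$cohort$genotypes
      pheno <- env$cohort$dogs$phenotype
      markers <- env$cohort$markers
    } else {
      geno <- env$genotypes; pheno <- env$phenotype; markers <- env$markers
    }
    qc <- qc_filter(geno, config$built$gwas)
    keep <- rownames(qc$genotypes)
    pheno <- pheno[match(keep, rownames(geno))]
    # relatedness from genome-background markers when available (the focal
    # region would otherwise dominate K and absorb the signal it should
    # only be correcting for)
    K <- if (!is.null(env$cohort) && !is.null(env$cohort$background))
      compute_grm(env$cohort$background[keep, , drop = FALSE])
    else NULL
    scan <- lmm_wald_scan(qc$genotypes, pheno, K = K,
                          config = config$built$gwas)
    hits <- classify_hits(scan, config$built$gwas)
    hits$pos <- markers$pos[match(hits$marker_id, markers$marker_id)]
    readr::write_tsv(hits, file.path(config$out_dir, "association.tsv"),
                     progress = FALSE)
    qq <- qq_data(scan)
    env$gwas_hits <- hits
    list(n_tested = sum(scan$ok), lambda_gc = qq$lambda_gc,
         qc = as.list(setNames(qc$report$removed, qc$report$step)),
         top_hits = head(dplyr::select(hits, "marker_id", "pos", "beta",
                                       "p_wald", "tier"), 5L))
  })

  run_stage("svdepth", function() {
    aln <- env$alignments %||% read_alignments(config$paths$alignments)
    rcfg <- config$built$reads
    region <- c(1L, rcfg$reference_length)
    profile <- scaled_window_depth(aln, region,
                                   window_bp = config$sv$window_bp,
                                   step_bp = config$sv$step_bp)
    clusters <- find_discordant_clusters(
      aln, min_support = config$sv$min_support,
      max_span_slop_bp = config$sv$max_span_slop_bp)
    calls <- call_tandem_duplication(profile, clusters,
                                     min_support = config$sv$min_support,
                                     min_ratio = config$sv$min_ratio)
    readr::write_tsv(profile, file.path(config$out_dir, "depth_profile.tsv"),
                     progress = FALSE)
    jsonlite::write_json(calls, file.path(config$out_dir, "dup_calls.json"),
                         digits = NA)
    if (nrow(calls) > 0L)
      writeLines(sprintf("chrS\t%d\t%d", calls$start - 1L, calls$end - 1L),
                 file.path(config$out_dir, "dup_calls.bed"))
    env$dup_calls <- calls
    list(n_clusters = nrow(clusters), calls = calls)
  })

  run_stage("intensity", function() {
    cohort <- env$cohort
    prof <- delta_logR(env$intensities,
                       dup_markers = cohort$markers$marker_id[
                         cohort$markers$in_dup],
                       flank_markers = flank_marker_set(
                         cohort$markers, c(cohort$dup_start, cohort$dup_end),
                         config$intensity$flank_window_bp))
    prof <- genotype_from_delta(prof,
                                het_threshold = config$intensity$het_threshold,
                                hom_threshold = config$intensity$hom_threshold)
    readr::write_tsv(prof, file.path(config$out_dir, "delta_logr.tsv"),
                     progress = FALSE)
    env$delta <- prof
    truth <- cohort$dogs$dup_copies
    cmp <- compare_delta_distributions(
      prof$delta_logR[truth >= 1L], prof$delta_logR[truth == 0L])
    list(class_counts = as.list(table(prof$copy_class)),
         concordance = mean(prof$copy_class == as.character(truth)),
         carrier_vs_noncarrier_p = cmp$p_value)
  })

  run_stage("haplotype", function() {
    cohort <- env$cohort
    hits <- env$gwas_hits
    index_pos <- if (!is.null(hits)) hits$pos[1L] else {
      mk <- cohort$markers
      mk$pos[mk$core & !mk$in_dup][1L]
    }
    idx <- match(index_pos, cohort$markers$pos)
    # homozygotes for the risk allele (alt if the top effect is positive);
    # when the intensity stage ran, additionally require a homozygous-
    # duplication delta log R class, which screens out phenocopies
    # homozygous for an imperfect tag allele
    risk_hom <- if (!is.null(hits) && is.finite(hits$beta[1L]) &&
                    hits$beta[1L] < 0) 0L else 2L
    is_case <- cohort$dogs$phenotype == 1L &
      cohort$genotypes[, idx] == risk_hom
    if (!is.null(env$delta)) {
      hom_dup <- env$delta$copy_class[match(cohort$dogs$dog_id,
                                            env$delta$dog_id)] == "2"
      if (sum(is_case & hom_dup) >= 2L) is_case <- is_case & hom_dup
    }
    cases <- cohort$dogs$dog_id[is_case]
    if (length(cases) < 2L)
      stop_bad_arg("fewer than 2 blue-eyed index homozygotes")
    shared <- find_shared_haplotype(cohort$haplotypes, cohort$markers,
                                    cases, index_pos)
    core <- define_core(cohort$haplotypes, cases, shared,
                        dup_interval = c(cohort$dup_start, cohort$dup_end))
    dosages <- count_core_copies(cohort$haplotypes, core)
    dosages <- dplyr::left_join(dosages, cohort$dogs, by = "dog_id")
    readr::write_tsv(dosages, file.path(config$out_dir, "dosages.tsv"),
                     progress = FALSE)
    assoc <- haplotype_association(dosages)
    pen <- penetrance_table(dosages)
    readr::write_tsv(pen, file.path(config$out_dir, "penetrance.tsv"),
                     progress = FALSE)
    list(core_span = c(core$span_start, core$span_end),
         core_markers = nrow(core$markers),
         core_excluded = sum(core$markers$excluded),
         association = assoc,
         case_coverage = case_coverage(dosages),
         penetrance = pen,
         modifier = modifier_test(dosages))
  })

  run_stage("variantqc", function() {
    panel <- simulate_variant_panel(env$cohort, config$n_variants,
                                    seed = config$seed)
    filt <- hard_filter(panel$variants, config$built$variants)
    excl <- carrier_exclusive(
      panel$genotypes[filt$variants$variant_id, , drop = FALSE],
      panel$carriers, panel$noncarriers)
    readr::write_tsv(filt$counts,
                     file.path(config$out_dir, "variant_filter_counts.tsv"),
                     progress = FALSE)
    list(n_input = nrow(panel$variants), n_pass = nrow(filt$variants),
         rule_counts = as.list(setNames(filt$counts$n_rejected,
                                        filt$counts$rule)),
         carrier_exclusive = excl)
  })

  out <- save_report()
  md <- c("# irisdup pipeline report",
          sprintf("- seed: %d", config$seed),
          sprintf("- stages: %s", paste(intersect(
            pipeline_defaults()$stages, names(report)), collapse = " -> ")))
  writeLines(md, file.path(config$out_dir, "report.md"))
  structure(out, class = "analysis_report")
}

#' Flank marker set around a duplication interval
#'
#' All markers within `window_bp` of the interval on either side, excluding
#' the interval itself.
#'
#' @param markers Tibble with `marker_id` and `pos`.
#' @param dup_interval Length-2 bp vector.
#' @param window_bp Window width per side (default 1 Mb).
#' @return Character vector of marker IDs.
#' @export
flank_marker_set <- function(markers, dup_interval, window_bp = 1e6) {
  sel <- (markers$pos >= dup_interval[1] - window_bp &
            markers$pos < dup_interval[1]) |
    (markers$pos > dup_interval[2] &
       markers$pos <= dup_interval[2] + window_bp)
  markers$marker_id[sel]
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  stages:", paste(setdiff(names(x), "provenance"), collapse = ", "),
      "\n")
  cat("  seed:", x$provenance$seed, " config:", x$provenance$config_hash,
      "\n")
  invisible(x)
}
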