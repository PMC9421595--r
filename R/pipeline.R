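#' Read and validate a pipeline run configuration
#'
#' The config is a YAML (or already-parsed list) with keys: `seed`
#' (mandatory), exactly one of `simulate` (synthetic-cohort block) or
#' `input` (paths: dosage, variants, sumstats, phenotypes), and optional
#' blocks `qc`, `clump` (`r2_max`, `window_kb`), `thresholds`, `apoe`
#' (`exclude`, `chrom`, `start`, `end`), `covariates`, `outcome`
#' (biomarker column, default ptau181), `mediation` (`model`, `n_boot`),
#' `decompose` (`enabled`, `model`, `alpha`, `n_boot_screen`, `order`) and
#' `output_dir`. Schema violations are aggregated into one error before any
#' computation.
#'
#' @param config path to a YAML file or a named list.
#' @return the validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errs <- character(0)
  if (is.null(config$seed)) errs <- c(errs, "seed is mandatory")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$input)
  if (has_sim == has_inp)
    errs <- c(errs, "exactly one of 'simulate' or 'input' must be given")
  if (has_inp) {
    need <- c("dosage", "variants", "sumstats", "phenotypes")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      errs <- c(errs, paste("input block lacks:", paste(miss, collapse = ", ")))
  }
  thr <- config$thresholds %||% c(0.05, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 5e-8)
  if (any(diff(thr) >= 0))
    errs <- c(errs, "thresholds must be strictly decreasing")
  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  config$thresholds <- thr
  config
}

sim_config_to_causal <- function(sim) {
  m <- sim$n_variants
  n_dep <- sim$n_dependent %||% 0
  n_ind <- sim$n_independent %||% 0
  ids <- sprintf("rs%05d", seq_len(m))
  causal_config(dependent_set = if (n_dep) ids[seq_len(n_dep)] else character(0),
                independent_set = if (n_ind) ids[n_dep + seq_len(n_ind)]
                else character(0),
                w_dep = sim$w_dep %||% 0.25, w_ind = sim$w_ind %||% 0.2,
                prevalence = sim$prevalence %||% 0.3,
                b_med = sim$b_med %||% 0.8)
}

#' Run the full pipeline from one configuration
#'
#' Stages, in order: simulate (or load) the cohort; variant QC; genotype
#' PCs; clumping + threshold-series PRS; association scans (unadjusted and
#' mediator-adjusted); bootstrap mediation of the chosen PRS on the outcome;
#' optional PRS decomposition. Every stage output is written as TSV/JSON
#' under `output_dir`, and a manifest (config hash, seed, per-file MD5
#' checksums, stage status) is written and returned. Reruns with the same
#' config and seed reproduce identical checksums. A stage failure is
#' recorded and all downstream stages are marked skipped.
#'
#' @param config config list or YAML path (see [read_run_config()]).
#' @param output_dir overrides `config$output_dir`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- read_run_config(config)
  out <- output_dir %||% config$output_dir %||% stop("output_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  cfg_hash <- config
  cfg_hash$output_dir <- NULL   # checksum must not depend on where we write
  manifest <- list(seed = seed, config_checksum = object_checksum(cfg_hash),
                   stages = list(), files = list())
  state <- new.env()
  failed <- FALSE

  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped: upstream failure")
      return(invisible(NULL))
    }
    res <- tryCatch({
      fun()
      list(status = "ok")
    }, error = function(e) {
      failed <<- TRUE
      list(status = paste("failed:", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- res
  }

  stage("data", function() {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cc <- sim_config_to_causal(sim)
      sc <- simulate_cohort(sim$n_individuals, sim$n_variants, cc,
                            gwas_n = sim$gwas_n %||% 50000,
                            ld_block_size = sim$ld_block_size %||% 1,
                            ld_rho = sim$ld_rho %||% 0,
                            missing_rate = sim$missing_rate %||% 0,
                            seed = seed)
      state$panel <- sc$panel; state$stats <- sc$stats
      state$cohort <- sc$cohort; state$truth <- sc$config
      write_panel(sc$panel, file.path(out, "panel"))
      write_summary_stats(sc$stats, file.path(out, "sumstats.tsv"))
      write_tsv(sc$cohort, file.path(out, "phenotypes.tsv"))
      jsonlite::write_json(unclass(sc$config),
                           file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      for (f in c("panel.dosage.tsv", "panel.variants.tsv", "sumstats.tsv",
                  "phenotypes.tsv", "ground_truth.json"))
        add_file(file.path(out, f))
    } else {
      state$panel <- read_dosage_panel(config$input$dosage,
                                       config$input$variants)
      state$stats <- read_summary_stats(config$input$sumstats)
      state$cohort <- utils::read.delim(config$input$phenotypes,
                                        stringsAsFactors = FALSE)
    }
  })

  stage("qc", function() {
    thr <- do.call(qc_thresholds, config$qc %||% list())
    res <- qc_filter(state$panel, thr)
    state$panel <- res$panel
    write_tsv(res$report, file.path(out, "qc_report.tsv"))
    add_file(file.path(out, "qc_report.tsv"))
  })

  stage("pcs", function() {
    k <- min(10, dim(state$panel) - 1)
    state$cohort <- add_pcs(state$cohort, state$panel, k = k)
    pcs <- state$cohort[, c("individual_id", paste0("PC", seq_len(k)))]
    write_tsv(pcs, file.path(out, "pcs.tsv"))
    add_file(file.path(out, "pcs.tsv"))
  })

  stage("prs", function() {
    apoe <- config$apoe %||% list()
    region <- if (!is.null(apoe$chrom))
      genomic_region(apoe$chrom, apoe$start, apoe$end) else apoe_region()
    models <- threshold_series(state$stats, state$panel,
                               thresholds = config$thresholds,
                               exclude_apoe = apoe$exclude %||% TRUE,
                               region = region,
                               r2_max = config$clump$r2_max %||% 0.1,
                               window_kb = config$clump$window_kb %||% 1000)
    state$models <- models
    tab <- data.frame(individual_id = names(models[[1]]$score))
    for (mod in models) tab[[mod$label]] <- unname(mod$score)
    write_tsv(tab, file.path(out, "prs.tsv"))
    counts <- data.frame(model = vapply(models, `[[`, "", "label"),
                         threshold = vapply(models, `[[`, 0, "threshold"),
                         n_variants = vapply(models, function(m)
                           length(m$variants), 0L))
    write_tsv(counts, file.path(out, "prs_counts.tsv"))
    add_file(file.path(out, "prs.tsv")); add_file(file.path(out, "prs_counts.tsv"))
  })

  stage("scan", function() {
    covs <- unlist(config$covariates) %||% NULL
    res <- rbind(assoc_scan(state$models, state$cohort, covariates = covs),
                 assoc_scan(state$models, state$cohort, covariates = covs,
                            adjust_for_mediator = TRUE))
    write_tsv(res, file.path(out, "associations.tsv"))
    add_file(file.path(out, "associations.tsv"))
    state$scan <- res
  })

  stage("mediation", function() {
    label <- config$mediation$model %||% "PRS1"
    mod <- state$models[[match(label, vapply(state$models, `[[`, "", "label"))]]
    outcome_col <- config$outcome %||% "ptau181"
    covs <- unlist(config$covariates) %||%
      default_covariates(state$cohort, mod$apoe_included)
    med <- mediate(mod, state$cohort$ab_status,
                   inverse_normal_transform(state$cohort[[outcome_col]]),
                   state$cohort[, covs, drop = FALSE],
                   n_boot = config$mediation$n_boot %||% 1000,
                   seed = derive_seed(seed, "mediation"))
    jsonlite::write_json(mediation_record(med),
                         file.path(out, "mediation.json"),
                         auto_unbox = TRUE, digits = NA)
    add_file(file.path(out, "mediation.json"))
    state$mediation <- med
  })

  stage("decompose", function() {
    dc <- config$decompose %||% list(enabled = FALSE)
    if (!isTRUE(dc$enabled)) return(invisible(NULL))
    label <- dc$model %||% "PRS1"
    mod <- state$models[[match(label, vapply(state$models, `[[`, "", "label"))]]
    res <- decompose_prs(mod, state$panel, state$cohort,
                         outcome_col = config$outcome %||% "ptau181",
                         alpha = dc$alpha %||% 0.05,
                         order = dc$order %||% "ascending",
                         n_boot_screen = dc$n_boot_screen %||% 200,
                         n_boot = dc$n_boot %||% 1000,
                         seed = derive_seed(seed, "decompose"))
    write_tsv(res$loo, file.path(out, "loo.tsv"))
    prof <- res$profile; class(prof) <- "data.frame"
    write_tsv(prof, file.path(out, "nested_profile.tsv"))
    writeLines(res$independent_subset, file.path(out, "independent_subset.txt"))
    writeLines(res$dependent_subset, file.path(out, "dependent_subset.txt"))
    val <- list(dependent_validation = res$dependent_validation[
      c("fit_mediator", "fit_unadj", "fit_adj")],
      mediation_independent = if (!is.null(res$mediation_independent))
        mediation_record(res$mediation_independent),
      mediation_dependent = if (!is.null(res$mediation_dependent))
        mediation_record(res$mediation_dependent),
      joint = res$joint)
    jsonlite::write_json(val, file.path(out, "decomposition.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (f in c("loo.tsv", "nested_profile.tsv", "independent_subset.txt",
                "dependent_subset.txt", "decomposition.json"))
      add_file(file.path(out, f))
    state$decomposition <- res
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
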