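#' Planted causal architecture for a synthetic cohort
#'
#' Describes which variants drive the binary amyloid mediator (the
#' "dependent" path), which drive the tau outcome directly (the
#' "independent" path), and how strongly, so downstream stages can be tested
#' against known ground truth. Effects are per standard deviation of
#' genotype: inside the phenotype models each dosage is standardized as
#' `z(G) = (G - 2 maf) / sqrt(2 maf (1 - maf))`.
#'
#' @param dependent_set variant ids whose standardized dosages enter the
#'   mediator liability only.
#' @param independent_set variant ids acting on the outcome directly only;
#'   must be disjoint from `dependent_set`.
#' @param w_dep,w_ind per-variant standardized effect sizes (recycled across
#'   the respective set).
#' @param prevalence mediator-positive fraction, strictly in (0, 1).
#' @param b_med standardized effect of the mediator on the outcome.
#' @param age_effect_med,sex_effect_med,age_effect_out,sex_effect_out
#'   covariate confounding effects (on standardized age and on sex coded
#'   0/1) for the mediator liability and the outcome.
#' @param sigma_med,sigma_out,sigma_ttau noise SDs for the mediator
#'   liability, the P-tau outcome, and the extra T-tau noise.
#' @param ab_cutoff CSF Abeta42/40 ratio cutoff reproduced by the mediator
#'   (default 0.091).
#' @param seed default seed carried with the configuration.
#' @return a `causal_config` list.
#' @export
causal_config <- function(dependent_set = character(0),
                          independent_set = character(0),
                          w_dep = 0.25, w_ind = 0.2,
                          prevalence = 0.3, b_med = 0.8,
                          age_effect_med = 0.1, sex_effect_med = 0.1,
                          age_effect_out = 0.1, sex_effect_out = 0.1,
                          sigma_med = 1, sigma_out = 1, sigma_ttau = 0.5,
                          ab_cutoff = 0.091, seed = 1L) {
  if (length(intersect(dependent_set, independent_set)))
    stop("dependent and independent variant sets must be disjoint")
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  effs <- c(w_dep, w_ind, b_med, age_effect_med, sex_effect_med,
            age_effect_out, sex_effect_out, sigma_med, sigma_out, sigma_ttau)
  if (any(!is.finite(effs))) stop("all effect sizes must be finite")
  structure(list(dependent_set = as.character(dependent_set),
                 independent_set = as.character(independent_set),
                 w_dep = rep_len(w_dep, max(1, length(dependent_set))),
                 w_ind = rep_len(w_ind, max(1, length(independent_set))),
                 prevalence = prevalence, b_med = b_med,
                 age_effect_med = age_effect_med,
                 sex_effect_med = sex_effect_med,
                 age_effect_out = age_effect_out,
                 sex_effect_out = sex_effect_out,
                 sigma_med = sigma_med, sigma_out = sigma_out,
                 sigma_ttau = sigma_ttau, ab_cutoff = ab_cutoff,
                 seed = as.integer(seed)),
            class = "causal_config")
}

check_config_panel <- function(config, panel) {
  miss <- setdiff(c(config$dependent_set, config$independent_set),
                  panel$variants$id)
  if (length(miss))
    stop("config references variants absent from the panel: ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}

# Non-strand-ambiguous allele pairs only, so harmonization never hits the
# A/T-C/G ambiguity in simulated data.
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate biallelic genotypes in HWE with block LD
#'
#' Haplotype-level first-order autoregressive Gaussian copula: within each
#' block of `ld_block_size` consecutive variants, a haplotype's latent
#' normals follow an AR(1) with parameter `ld_rho`, and the allele is the
#' indicator that the latent value falls below the MAF quantile. Blocks are
#' independent; two haplotypes per individual are drawn independently, so
#' marginal genotype frequencies satisfy HWE at the drawn MAF. Blocks are
#' laid out cyclically over chromosomes 1-22 at 50 kb spacing.
#'
#' @param n_individuals,n_variants panel dimensions (>= 2 and >= 1).
#' @param maf_range MAF bounds, ordered, within [0.05, 0.5]; per-variant MAF
#'   is uniform on this range.
#' @param ld_block_size variants per LD block (1 = independent variants).
#' @param ld_rho latent AR(1) correlation in [0, 1).
#' @param missing_rate probability of a missing dosage, completely at random.
#' @param seed RNG seed.
#' @return a `genotype_panel`.
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.05, 0.5),
                               ld_block_size = 1, ld_rho = 0,
                               missing_rate = 0, seed = 1L) {
  if (n_individuals < 2 || n_variants < 1 || ld_block_size < 1)
    stop("need n_individuals >= 2, n_variants >= 1, ld_block_size >= 1")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0.05 || maf_range[2] > 0.5)
    stop("maf_range must be ordered and lie within [0.05, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  set.seed(seed)
  m <- n_variants
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  block <- (seq_len(m) - 1) %/% ld_block_size + 1
  nh <- 2 * n_individuals
  latent <- matrix(NA_real_, nh, m)
  for (j in seq_len(m)) {
    if (j > 1 && block[j] == block[j - 1]) {
      latent[, j] <- ld_rho * latent[, j - 1] +
        sqrt(1 - ld_rho^2) * stats::rnorm(nh)
    } else {
      latent[, j] <- stats::rnorm(nh)
    }
  }
  thr <- stats::qnorm(maf)
  hap <- sweep(latent, 2, thr, `<`) * 1
  dosage <- hap[seq_len(n_individuals), , drop = FALSE] +
    hap[n_individuals + seq_len(n_individuals), , drop = FALSE]
  if (missing_rate > 0)
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA_real_
  chrom <- as.character((block - 1) %% 22 + 1)
  pos <- integer(m)
  for (cc in unique(chrom)) {
    w <- chrom == cc
    pos[w] <- 1e6 + (seq_len(sum(w)) - 1) * 5e4
  }
  alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                           drop = FALSE]
  variants <- data.frame(id = sprintf("rs%05d", seq_len(m)), chrom = chrom,
                         pos = pos, a1 = alleles[, 1], a2 = alleles[, 2],
                         stringsAsFactors = FALSE)
  genotype_panel(dosage, variants,
                 sprintf("ind%05d", seq_len(n_individuals)))
}

#' Simulate case-control GWAS summary statistics over a panel
#'
#' Each variant's estimate is its true standardized effect (from the causal
#' configuration; zero for null variants) plus Gaussian sampling noise with
#' `SE = 1 / sqrt(2 n maf (1 - maf))`, the usual large-sample scaling of a
#' per-allele GWAS coefficient. P-values are two-sided normal on
#' estimate/SE.
#'
#' @param panel a `genotype_panel`.
#' @param config a `causal_config`; its variant sets must exist in the panel.
#' @param gwas_n discovery-sample size controlling the SE.
#' @param noise_scale multiplier on the sampling noise (0 = estimates equal
#'   the true effects exactly; useful for deterministic checks).
#' @param seed RNG seed.
#' @return a `summary_stats` object with one row per panel variant.
#' @export
simulate_summary_stats <- function(panel, config, gwas_n = 50000,
                                   noise_scale = 1, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "causal_config"))
  check_config_panel(config, panel)
  set.seed(seed)
  ids <- panel$variants$id
  maf <- panel_maf(panel)
  maf <- pmin(pmax(maf, 1e-6), 0.5)
  beta_true <- stats::setNames(rep(0, length(ids)), ids)
  beta_true[config$dependent_set] <- rep_len(config$w_dep,
                                             length(config$dependent_set))
  beta_true[config$independent_set] <- rep_len(config$w_ind,
                                               length(config$independent_set))
  se <- 1 / sqrt(2 * gwas_n * maf * (1 - maf))
  est <- beta_true + stats::rnorm(length(ids)) * se * noise_scale
  z <- est / se
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  summary_stats(data.frame(id = ids, chrom = panel$variants$chrom,
                           pos = panel$variants$pos, a1 = panel$variants$a1,
                           a2 = panel$variants$a2, beta = unname(est),
                           se = unname(se), p = unname(p),
                           stringsAsFactors = FALSE))
}

#' Simulate mediated biomarker phenotypes and covariates
#'
#' The binary amyloid mediator comes from a liability threshold: liability =
#' planted dependent-variant effects on standardized dosages + covariate
#' terms + noise, dichotomized at its empirical `1 - prevalence` quantile.
#' CSF P-tau181 = `b_med * mediator` + planted independent-variant effects +
#' covariate terms + noise; T-tau adds independent noise to the same latent
#' signal. NfL, Abeta1-38 and Abeta1-40 carry no variant effects (null
#' biomarkers). Abeta1-42 is constructed so that dichotomizing Abeta42/40 at
#' the configured cutoff (low ratio = pathologic) reproduces the mediator
#' exactly. Covariates: age ~ U(60, 85), sex ~ Bernoulli(0.5), education ~
#' U(6, 20), MMSE ~ uniform on 24-30, APOE e4/e2 counts from HWE at allele
#' frequencies 0.15 and 0.08.
#'
#' @param panel a `genotype_panel`.
#' @param config a `causal_config`.
#' @param seed RNG seed.
#' @return data.frame (one row per individual): individual_id, biomarkers
#'   (ttau, ptau181, ab38, ab40, ab42, nfl, ab_ratio), covariates (age, sex,
#'   education, mmse, apoe4_count, apoe2_count), strata (dx_group,
#'   apoe4_status) and the binary mediator `ab_status`.
#' @export
simulate_phenotypes <- function(panel, config, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "causal_config"))
  check_config_panel(config, panel)
  set.seed(seed)
  n <- nrow(panel$dosage)
  age <- stats::runif(n, 60, 85)
  sex <- stats::rbinom(n, 1, 0.5)
  education <- stats::runif(n, 6, 20)
  mmse <- sample(24:30, n, replace = TRUE)
  apoe4 <- stats::rbinom(n, 2, 0.15)
  apoe2 <- stats::rbinom(n, 2, 0.08)
  dx_group <- sample(c("CU", "MCI", "AD"), n, replace = TRUE,
                     prob = c(0.55, 0.30, 0.15))
  z_age <- standardize(age)
  genetic_term <- function(ids, w) {
    if (!length(ids)) return(rep(0, n))
    g <- panel$dosage[, match(ids, panel$variants$id), drop = FALSE]
    zg <- apply(g, 2, scale_dosage)
    drop(zg %*% rep_len(w, length(ids)))
  }
  liability <- genetic_term(config$dependent_set, config$w_dep) +
    config$age_effect_med * z_age + config$sex_effect_med * (sex - 0.5) +
    stats::rnorm(n, 0, config$sigma_med)
  mediator <- as.integer(liability >
                           stats::quantile(liability, 1 - config$prevalence))
  latent <- config$b_med * mediator +
    genetic_term(config$independent_set, config$w_ind) +
    config$age_effect_out * z_age + config$sex_effect_out * (sex - 0.5) +
    stats::rnorm(n, 0, config$sigma_out)
  ptau181 <- 45 + 18 * latent
  ttau <- 300 + 120 * (latent + stats::rnorm(n, 0, config$sigma_ttau))
  nfl <- 800 + 15 * (age - 60) + stats::rnorm(n, 0, 200)
  ab38 <- stats::rnorm(n, 2200, 300)
  ab40 <- pmax(stats::rnorm(n, 15000, 2000), 1000)
  u <- stats::runif(n, 0.1, 0.6)
  ratio <- ifelse(mediator == 1, config$ab_cutoff * (1 - u),
                  config$ab_cutoff * (1 + u))
  ab42 <- ratio * ab40
  data.frame(individual_id = rownames(panel$dosage),
             ttau = ttau, ptau181 = ptau181, ab38 = ab38, ab40 = ab40,
             ab42 = ab42, nfl = nfl, ab_ratio = ratio,
             age = age, sex = sex, education = education, mmse = mmse,
             apoe4_count = apoe4, apoe2_count = apoe2,
             dx_group = dx_group,
             apoe4_status = ifelse(apoe4 > 0, "positive", "negative"),
             ab_status = mediator, stringsAsFactors = FALSE)
}

#' Simulate a full cohort: genotypes, summary stats, phenotypes
#'
#' Convenience wrapper drawing the three components with seeds derived from
#' one root seed, and carrying the ground-truth configuration alongside.
#'
#' @param n_individuals,n_variants panel dimensions.
#' @param config a `causal_config` (variant ids must match the simulated
#'   panel's `rs%05d` naming).
#' @param gwas_n discovery-GWAS size for the summary statistics.
#' @param maf_range,ld_block_size,ld_rho,missing_rate passed to
#'   [simulate_genotypes()].
#' @param seed root seed; stage seeds are derived deterministically.
#' @return a `synthetic_cohort` list: `panel`, `stats`, `cohort`, `config`.
#' @export
simulate_cohort <- function(n_individuals, n_variants,
                            config = causal_config(), gwas_n = 50000,
                            maf_range = c(0.05, 0.5), ld_block_size = 1,
                            ld_rho = 0, missing_rate = 0,
                            seed = config$seed) {
  panel <- simulate_genotypes(n_individuals, n_variants,
                              maf_range = maf_range,
                              ld_block_size = ld_block_size, ld_rho = ld_rho,
                              missing_rate = missing_rate,
                              seed = derive_seed(seed, "genotypes"))
  stats <- simulate_summary_stats(panel, config, gwas_n = gwas_n,
                                  seed = derive_seed(seed, "sumstats"))
  cohort <- simulate_phenotypes(panel, config,
                                seed = derive_seed(seed, "phenotypes"))
  structure(list(panel = panel, stats = stats, cohort = cohort,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$panel$dosage), "individuals,",
      ncol(x$panel$dosage), "variants\n")
  cat("  planted: ", length(x$config$dependent_set), " mediator-path, ",
      length(x$config$independent_set), " direct-path variants; prevalence ",
      x$config$prevalence, "\n", sep = "")
  invisible(x)
}

#' Append genotype principal components to a cohort table
#' @param cohort cohort data.frame with `individual_id`.
#' @param panel the matching `genotype_panel`.
#' @param k number of PCs (default 10).
#' @return the cohort with columns `PC1..PCk` appended.
#' @export
add_pcs <- function(cohort, panel, k = 10) {
  pcs <- compute_pcs(panel, k)
  idx <- match(cohort$individual_id, rownames(pcs))
  if (anyNA(idx)) stop("cohort individuals missing from the panel")
  cbind(cohort, as.data.frame(pcs[idx, , drop = FALSE]))
}
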