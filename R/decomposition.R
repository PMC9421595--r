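# Decomposition of a PRS into mediator-independent and exclusive
# mediator-dependent variant subsets, by leave-one-out screening against the
# mediator and nested re-scoring with per-model mediation tests.

# Mean-imputed dosage submatrix for a weight vector, columns in weight order.
weighted_dosage <- function(panel, weights) {
  idx <- match(names(weights), panel$variants$id)
  if (anyNA(idx))
    stop("weights reference variants absent from the panel: ",
         paste(utils::head(names(weights)[is.na(idx)], 5), collapse = ", "))
  g <- panel$dosage[, idx, drop = FALSE]
  if (anyNA(g)) {
    cm <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- cm[nas[, 2]]
  }
  g
}

# Linear-probability (or plain OLS) p-value of a standardized score against
# a response, given a covariate matrix.
score_term <- function(score, response, cov_m) {
  ols_term(cbind(1, standardize(score), cov_m), response, 2)
}

#' Leave-one-out screen of PRS variants against the mediator
#'
#' For each variant in the PRS, rebuilds the score from the remaining n-1
#' variants (same weights), standardizes it, and records the p-value of its
#' linear-probability association with the binary mediator, adjusted for the
#' covariates. The direction flag says whether removing the variant
#' strengthened (smaller p than the full PRS) or weakened the PRS-mediator
#' association.
#'
#' @param weights named per-variant weight vector of the full PRS (>= 2
#'   variants).
#' @param panel a `genotype_panel`.
#' @param mediator binary vector over the panel's individuals.
#' @param covariates data.frame/matrix of covariates, or `NULL`.
#' @return data.frame: id, p_loo, beta_loo, p_full, direction
#'   (strengthened/weakened/unchanged).
#' @export
loo_scan <- function(weights, panel, mediator, covariates = NULL) {
  if (length(weights) < 2)
    stop("leave-one-out needs a PRS with at least 2 variants")
  g <- weighted_dosage(panel, weights)
  cov_m <- if (is.null(covariates)) matrix(numeric(0), nrow(g), 0)
  else as.matrix(as.data.frame(covariates))
  full_raw <- drop(g %*% unname(weights))
  full <- score_term(full_raw, mediator, cov_m)
  out <- lapply(seq_along(weights), function(i) {
    loo_raw <- full_raw - g[, i] * weights[i]
    fit <- score_term(loo_raw, mediator, cov_m)
    data.frame(id = names(weights)[i], p_loo = fit$p, beta_loo = fit$beta,
               p_full = full$p,
               direction = if (fit$p < full$p) "strengthened"
               else if (fit$p > full$p) "weakened" else "unchanged",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank leave-one-out records by mediator-association p-value
#'
#' Ascending order puts first the variant whose removal left the strongest
#' PRS-mediator association (the most mediator-independent variant), feeding
#' the independent-subset search; descending feeds the dependent-subset
#' search. Ties break by variant id, so the order is deterministic.
#'
#' @param records output of [loo_scan()].
#' @param order `"ascending"` (default) or `"descending"`.
#' @return character vector of variant ids in rank order.
#' @export
rank_variants <- function(records, order = c("ascending", "descending")) {
  order <- match.arg(order)
  if (!nrow(records)) stop("no records to rank")
  o <- if (order == "ascending") base::order(records$p_loo, records$id)
  else base::order(-records$p_loo, records$id)
  records$id[o]
}

#' Nested PRS profile along a variant ranking
#'
#' For each k, scores the top-k variants (original weights, re-standardized
#' per k), fits the outcome association unadjusted and mediator-adjusted,
#' and runs a screening bootstrap mediation. A k whose score has zero
#' variance is flagged skipped.
#'
#' @param ranked_ids complete ranking of the PRS variants.
#' @param weights named weight vector covering `ranked_ids`.
#' @param panel a `genotype_panel`.
#' @param outcome numeric outcome vector (INT biomarker).
#' @param mediator binary mediator vector.
#' @param covariates data.frame/matrix or `NULL`.
#' @param n_boot_screen bootstrap resamples per k during screening
#'   (default 200; final subsets should be re-validated at 1000).
#' @param seed root seed; each k gets a derived stream.
#' @return a `nested_profile` data.frame, one row per k: variant_added,
#'   beta_unadj, p_unadj, beta_adj, p_adj, indirect, ci bounds, p_med,
#'   proportion_mediated, status; attribute `ranked_ids`.
#' @export
nested_profile <- function(ranked_ids, weights, panel, outcome, mediator,
                           covariates = NULL, n_boot_screen = 200,
                           seed = 1L) {
  if (!setequal(ranked_ids, names(weights)) ||
      length(ranked_ids) != length(weights))
    stop("ranked_ids must be a permutation of the weighted variants")
  w <- weights[ranked_ids]
  g <- weighted_dosage(panel, w)
  cov_m <- if (is.null(covariates)) matrix(numeric(0), nrow(g), 0)
  else as.matrix(as.data.frame(covariates))
  raw <- rep(0, nrow(g))
  rows <- vector("list", length(w))
  for (k in seq_along(w)) {
    raw <- raw + g[, k] * w[k]
    if (stats::sd(raw) == 0) {
      rows[[k]] <- data.frame(k = k, variant_added = ranked_ids[k],
                              beta_unadj = NA, p_unadj = NA, beta_adj = NA,
                              p_adj = NA, indirect = NA, ci_lower = NA,
                              ci_upper = NA, p_med = NA,
                              proportion_mediated = NA,
                              status = "skipped: zero-variance score",
                              stringsAsFactors = FALSE)
      next
    }
    sc <- standardize(raw)
    unadj <- score_term(raw, outcome, cov_m)
    adj <- score_term(raw, outcome, cbind(mediator, cov_m))
    med <- mediate(sc, mediator, outcome, cov_m, n_boot = n_boot_screen,
                   seed = derive_seed(seed, paste0("nested", k)))
    rows[[k]] <- data.frame(k = k, variant_added = ranked_ids[k],
                            beta_unadj = unadj$beta, p_unadj = unadj$p,
                            beta_adj = adj$beta, p_adj = adj$p,
                            indirect = med$indirect,
                            ci_lower = med$ci[1], ci_upper = med$ci[2],
                            p_med = med$p_boot,
                            proportion_mediated = med$proportion_mediated,
                            status = "ok", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "ranked_ids") <- ranked_ids
  class(out) <- c("nested_profile", "data.frame")
  out
}

#' Select mediator-independent candidate PRSs from a nested profile
#'
#' Candidates are the k whose nested PRS shows no significant mediation
#' (bootstrap p >= alpha) while still predicting the outcome significantly
#' both unadjusted and mediator-adjusted (p < alpha for both). The optimal
#' independent subset is the candidate minimizing |beta_adj - beta_unadj|
#' (ties to the larger k). An empty candidate list is a valid result.
#'
#' @param profile a `nested_profile`.
#' @param alpha screening level (default 0.05).
#' @return list: `candidate_ks`, `optimal_k` (NA when none), `optimal_subset`
#'   (ids), `candidate_union` (ids in any candidate PRS).
#' @export
select_independent <- function(profile, alpha = 0.05) {
  stopifnot(inherits(profile, "nested_profile"))
  ranked <- attr(profile, "ranked_ids")
  ok <- profile$status == "ok"
  cand <- which(ok & profile$p_med >= alpha &
                  profile$p_unadj < alpha & profile$p_adj < alpha)
  if (!length(cand))
    return(list(candidate_ks = integer(0), optimal_k = NA_integer_,
                optimal_subset = character(0), candidate_union = character(0)))
  gap <- abs(profile$beta_adj[cand] - profile$beta_unadj[cand])
  best <- cand[base::order(gap, -profile$k[cand])][1]
  list(candidate_ks = profile$k[cand], optimal_k = profile$k[best],
       optimal_subset = ranked[seq_len(profile$k[best])],
       candidate_union = ranked[seq_len(max(profile$k[cand]))])
}

#' Exclusive mediator-dependent complement of the independent candidates
#'
#' The variants belonging to no mediator-independent candidate PRS. When a
#' panel and phenotypes are supplied, the subset-PRS is validated: its
#' association with the mediator, with the outcome unadjusted, and with the
#' outcome mediator-adjusted (the expected pattern is collapse on
#' adjustment).
#'
#' @param weights full-PRS named weight vector.
#' @param candidate_union ids in any independent candidate set.
#' @param panel,outcome,mediator,covariates optional validation inputs.
#' @return list: `ids`, and (when validated) `fit_mediator`, `fit_unadj`,
#'   `fit_adj`.
#' @export
exclusive_dependent <- function(weights, candidate_union, panel = NULL,
                                outcome = NULL, mediator = NULL,
                                covariates = NULL) {
  extra <- setdiff(candidate_union, names(weights))
  if (length(extra))
    stop("candidate sets are not subsets of the full PRS: ",
         paste(utils::head(extra, 5), collapse = ", "))
  ids <- setdiff(names(weights), candidate_union)
  out <- list(ids = ids)
  if (!length(ids)) {
    warning("independent candidates cover the full PRS; no dependent component identified")
    return(out)
  }
  if (!is.null(panel)) {
    g <- weighted_dosage(panel, weights[ids])
    raw <- drop(g %*% unname(weights[ids]))
    cov_m <- if (is.null(covariates)) matrix(numeric(0), nrow(g), 0)
    else as.matrix(as.data.frame(covariates))
    out$fit_mediator <- score_term(raw, mediator, cov_m)
    out$fit_unadj <- score_term(raw, outcome, cov_m)
    out$fit_adj <- score_term(raw, outcome, cbind(mediator, cov_m))
  }
  out
}

#' Joint model with both PRS subsets as simultaneous predictors
#'
#' Enters the independent-subset PRS and the dependent-subset PRS (each
#' standardized) together with the covariates, unadjusted and
#' mediator-adjusted; reports the coefficient of each subset in each model.
#'
#' @param independent_ids,dependent_ids disjoint, non-empty variant id sets.
#' @param weights full-PRS named weight vector.
#' @param panel a `genotype_panel`.
#' @param outcome,mediator,covariates phenotype inputs as elsewhere.
#' @return data.frame with one row per (subset, adjustment): beta, se, p.
#' @export
joint_model <- function(independent_ids, dependent_ids, weights, panel,
                        outcome, mediator, covariates = NULL) {
  if (!length(independent_ids) || !length(dependent_ids))
    stop("both subsets must be non-empty")
  if (length(intersect(independent_ids, dependent_ids)))
    stop("subsets must be disjoint")
  s_ind <- standardize(drop(weighted_dosage(panel, weights[independent_ids]) %*%
                              unname(weights[independent_ids])))
  s_dep <- standardize(drop(weighted_dosage(panel, weights[dependent_ids]) %*%
                              unname(weights[dependent_ids])))
  cov_m <- if (is.null(covariates)) matrix(numeric(0), length(outcome), 0)
  else as.matrix(as.data.frame(covariates))
  fit_pair <- function(adjusted) {
    X <- if (adjusted) cbind(1, s_ind, s_dep, mediator, cov_m)
    else cbind(1, s_ind, s_dep, cov_m)
    rbind(
      data.frame(subset = "independent", mediator_adjusted = adjusted,
                 beta = ols_term(X, outcome, 2)$beta,
                 se = ols_term(X, outcome, 2)$se,
                 p = ols_term(X, outcome, 2)$p),
      data.frame(subset = "dependent", mediator_adjusted = adjusted,
                 beta = ols_term(X, outcome, 3)$beta,
                 se = ols_term(X, outcome, 3)$se,
                 p = ols_term(X, outcome, 3)$p))
  }
  out <- rbind(fit_pair(FALSE), fit_pair(TRUE))
  rownames(out) <- NULL
  out
}

#' Decompose a PRS into mediator-independent and exclusive
#' mediator-dependent variant subsets
#'
#' Runs the full heuristic on one PRS model: (1) leave-one-out screen of
#' every variant against the binary amyloid mediator; (2) rank variants by
#' the leave-one-out p-value (ascending by default: most
#' mediator-independent first); (3) rebuild nested top-k PRSs along the
#' ranking, testing each against the outcome with and without mediator
#' adjustment plus a screening bootstrap mediation; (4) keep as
#' "independent candidates" the k with no significant mediation but a
#' significant outcome effect both ways, pick the optimal one (smallest
#' adjusted-vs-unadjusted coefficient change), and (5) define the exclusive
#' dependent subset as the variants in no candidate PRS, re-validating both
#' subsets and their joint two-PRS model with full-size bootstraps.
#'
#' @param model a `prs_model` (the full PRS to decompose).
#' @param panel a `genotype_panel`.
#' @param cohort cohort data.frame with the outcome column, `ab_status`, and
#'   covariates.
#' @param outcome_col biomarker column to explain (default `"ptau181"`,
#'   inverse-normal transformed internally).
#' @param covariates covariate column names; default
#'   [default_covariates()] of the cohort.
#' @param alpha screening level (default 0.05).
#' @param order leave-one-out ranking order (default `"ascending"`).
#' @param n_boot_screen screening bootstraps per nested model (default 200).
#' @param n_boot full bootstraps for the final validations (default 1000).
#' @param seed root seed.
#' @return an object of class `prs_decomposition`: `loo`, `ranked_ids`,
#'   `profile`, `selection`, `independent_subset`, `dependent_subset`,
#'   `dependent_validation`, `mediation_independent`, `mediation_dependent`,
#'   `joint`, plus the call parameters.
#' @export
decompose_prs <- function(model, panel, cohort, outcome_col = "ptau181",
                          covariates = NULL, alpha = 0.05,
                          order = "ascending", n_boot_screen = 200,
                          n_boot = 1000, seed = 1L) {
  stopifnot(inherits(model, "prs_model"))
  weights <- model$weights
  if (length(weights) < 2) stop("PRS must contain at least 2 variants")
  covs <- covariates %||% default_covariates(cohort, model$apoe_included)
  cov_df <- cohort[, covs, drop = FALSE]
  outcome <- inverse_normal_transform(cohort[[outcome_col]])
  mediator <- cohort$ab_status
  loo <- loo_scan(weights, panel, mediator, cov_df)
  ranked <- rank_variants(loo, order)
  profile <- nested_profile(ranked, weights, panel, outcome, mediator,
                            cov_df, n_boot_screen = n_boot_screen,
                            seed = derive_seed(seed, "profile"))
  sel <- select_independent(profile, alpha)
  dep <- exclusive_dependent(weights, sel$candidate_union, panel, outcome,
                             mediator, cov_df)
  med_ind <- med_dep <- joint <- NULL
  if (length(sel$optimal_subset)) {
    s <- standardize(drop(weighted_dosage(panel, weights[sel$optimal_subset]) %*%
                            unname(weights[sel$optimal_subset])))
    med_ind <- mediate(s, mediator, outcome, cov_df, n_boot = n_boot,
                       seed = derive_seed(seed, "validate_ind"))
  }
  if (length(dep$ids)) {
    s <- standardize(drop(weighted_dosage(panel, weights[dep$ids]) %*%
                            unname(weights[dep$ids])))
    med_dep <- mediate(s, mediator, outcome, cov_df, n_boot = n_boot,
                       seed = derive_seed(seed, "validate_dep"))
  }
  if (length(sel$optimal_subset) && length(dep$ids)) {
    joint <- joint_model(sel$optimal_subset, dep$ids, weights, panel,
                         outcome, mediator, cov_df)
  }
  structure(list(loo = loo, ranked_ids = ranked, profile = profile,
                 selection = sel, independent_subset = sel$optimal_subset,
                 dependent_subset = dep$ids, dependent_validation = dep,
                 mediation_independent = med_ind,
                 mediation_dependent = med_dep, joint = joint,
                 alpha = alpha, order = order, seed = seed,
                 model_label = model$label),
            class = "prs_decomposition")
}

#' @export
print.prs_decomposition <- function(x, ...) {
  n <- nrow(x$loo)
  cat("PRS decomposition of", x$model_label, "(", n, "variants )\n")
  cat("  leave-one-out: ", sum(x$loo$direction == "strengthened"),
      "strengthened /", sum(x$loo$direction == "weakened"),
      "weakened the mediator association on removal\n")
  cat("  independent candidates:", length(x$selection$candidate_ks),
      "nested models; optimal k =", x$selection$optimal_k, "\n")
  cat("  optimal independent subset:", length(x$independent_subset),
      "variants; exclusive dependent subset:", length(x$dependent_subset),
      "variants\n")
  dv <- x$dependent_validation
  if (!is.null(dv$fit_unadj)) {
    cat(sprintf("  dependent-subset PRS on outcome: beta %.3f (p %.2g) -> %.3f (p %.2g) after mediator adjustment\n",
                dv$fit_unadj$beta, dv$fit_unadj$p, dv$fit_adj$beta,
                dv$fit_adj$p))
  }
  invisible(x)
}
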