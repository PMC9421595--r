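#' Rank-based inverse normal transformation
#'
#' Maps the non-missing values through their ranks to normal quantiles:
#' rank r of n becomes `qnorm((r - offset) / (n - 2*offset + 1))` with the
#' Blom offset 3/8 by default, i.e. `qnorm((r - 3/8) / (n + 1/4))`. Ties get
#' average ranks; missing values stay missing. The transform is monotone, so
#' ranks are preserved.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param offset rank offset (default 3/8, Blom).
#' @return transformed vector, same length and NA pattern.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2)
    stop("inverse normal transform needs at least 2 distinct non-missing values")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (length(x) - 2 * offset + 1))
  out
}

new_assoc_result <- function(model, biomarker, beta, se, statistic, p, n,
                             family, mediator_adjusted = FALSE,
                             stratum = NA_character_, status = "ok") {
  data.frame(model = model, biomarker = biomarker, stratum = stratum,
             beta = beta, se = se, statistic = statistic, p = p, n = n,
             family = family, mediator_adjusted = mediator_adjusted,
             bonferroni_sig = NA, status = status,
             stringsAsFactors = FALSE)
}

# Build [intercept | exposure | covariates] over complete cases; errors on
# rank deficiency naming the offending columns.
build_design <- function(y, exposure, covariates) {
  if (inherits(exposure, "prs_model")) exposure <- exposure$score
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    covariates <- as.matrix(as.data.frame(covariates))
  }
  X <- cbind(`(Intercept)` = 1, exposure = exposure, covariates)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(X = X, y = y, n = length(y))
}

#' Covariate-adjusted linear association of a biomarker with a PRS
#'
#' Ordinary least squares of `y` on the PRS and covariates (with intercept);
#' the reported coefficient, SE and two-sided t-test refer to the PRS term.
#'
#' @param y numeric outcome (typically already inverse-normal transformed).
#' @param prs numeric exposure vector or a `prs_model` (its standardized
#'   score is used).
#' @param covariates data.frame or matrix of covariate columns, or `NULL`.
#' @param model,biomarker labels carried into the result row.
#' @param mediator_adjusted label flag carried into the result row.
#' @return a one-row association data.frame (beta, se, statistic, p, n, ...).
#' @export
linear_assoc <- function(y, prs, covariates = NULL, model = "PRS",
                         biomarker = "biomarker", mediator_adjusted = FALSE) {
  d <- build_design(y, prs, covariates)
  if (d$n < ncol(d$X) + 2)
    stop("too few complete cases (", d$n, ") for ", ncol(d$X), " predictors")
  fit <- stats::lm.fit(d$X, d$y)
  df <- d$n - ncol(d$X)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(xtx_inv) * rss / df)
  beta <- fit$coefficients["exposure"]
  se_b <- se[match("exposure", colnames(d$X))]
  tval <- beta / se_b
  p <- 2 * stats::pt(-abs(tval), df)
  new_assoc_result(model, biomarker, unname(beta), unname(se_b),
                   unname(tval), unname(p), d$n, "linear", mediator_adjusted)
}

#' Covariate-adjusted logistic association of a binary status with a PRS
#'
#' Maximum-likelihood logistic regression; the Wald coefficient, SE and
#' two-sided p refer to the PRS term. Perfect separation (diverging
#' coefficient with fitted probabilities at 0/1) is an error: penalized
#' likelihood is out of scope here.
#'
#' @inheritParams linear_assoc
#' @param y binary outcome vector (both classes must be present).
#' @return a one-row association data.frame.
#' @export
logistic_assoc <- function(y, prs, covariates = NULL, model = "PRS",
                           biomarker = "biomarker",
                           mediator_adjusted = FALSE) {
  d <- build_design(y, prs, covariates)
  if (length(unique(d$y)) < 2)
    stop("binary outcome must include both classes")
  fit <- suppressWarnings(
    stats::glm.fit(d$X, d$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  if (any(abs(fit$coefficients) > 12) && any(mu < 1e-8 | mu > 1 - 1e-8))
    stop("perfect separation detected; penalized logistic regression is out of scope")
  w <- mu * (1 - mu)
  info <- crossprod(d$X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  j <- match("exposure", colnames(d$X))
  beta <- fit$coefficients[j]
  zval <- beta / se[j]
  p <- 2 * stats::pnorm(-abs(zval))
  new_assoc_result(model, biomarker, unname(beta), unname(se[j]),
                   unname(zval), unname(p), d$n, "logistic",
                   mediator_adjusted)
}

#' Dichotomize amyloid status from the CSF Abeta42/40 ratio
#'
#' Default direction `"low"`: a ratio strictly below the cutoff is
#' pathologic (the biologically standard reading). `direction = "high"`
#' flips the comparison (ratio strictly above the cutoff pathologic). A
#' ratio exactly at the cutoff is non-pathologic under either direction
#' (strict inequality).
#'
#' @param ab42,ab40 concentration vectors; `ab40` must be positive.
#' @param cutoff ratio cutoff (default 0.091).
#' @param direction `"low"` or `"high"`.
#' @return integer vector, 1 = pathologic.
#' @export
dichotomize_ab <- function(ab42, ab40, cutoff = 0.091,
                           direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (any(ab40 <= 0, na.rm = TRUE)) stop("ab40 must be strictly positive")
  ratio <- ab42 / ab40
  if (direction == "low") as.integer(ratio < cutoff)
  else as.integer(ratio > cutoff)
}

default_covariates <- function(cohort, apoe_included = FALSE) {
  std <- c("age", "sex", "education", "mmse",
           if (!apoe_included) c("apoe4_count", "apoe2_count"),
           paste0("PC", 1:10))
  intersect(std, names(cohort))
}

#' Association scan of PRS models against CSF biomarkers
#'
#' For each (model, biomarker[, stratum]) cell: continuous biomarkers are
#' inverse-normal transformed and fitted by [linear_assoc()]; the Abeta42/40
#' ratio is dichotomized (see [dichotomize_ab()]) and fitted by
#' [logistic_assoc()]. Covariates default to age, sex, education, MMSE,
#' APOE e4/e2 counts (dropped for APOE-region-inclusive models) and PC1-10,
#' restricted to columns present in the cohort; with
#' `adjust_for_mediator = TRUE` the binary amyloid status is appended.
#' Bonferroni flags are set within each (biomarker, stratum,
#' mediator-adjustment) family, with m = number of PRS models tested.
#' Strata cells with too few rows are emitted with status
#' `"skipped: insufficient n"`.
#'
#' @param models list of `prs_model` objects (or a single one).
#' @param cohort cohort data.frame (see [simulate_phenotypes()] for the
#'   column dialect).
#' @param biomarkers biomarker columns to scan.
#' @param adjust_for_mediator append `ab_status` to the covariates.
#' @param strata optional cohort column name to stratify on (e.g.
#'   `"dx_group"` or `"apoe4_status"`).
#' @param covariates covariate column names; default as described.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param cutoff,direction passed to [dichotomize_ab()] for the ratio.
#' @return data.frame of association rows, one per scan cell.
#' @export
assoc_scan <- function(models, cohort,
                       biomarkers = c("ttau", "ptau181", "ab38", "ab40",
                                      "ab42", "nfl", "ab_ratio"),
                       adjust_for_mediator = FALSE, strata = NULL,
                       covariates = NULL, alpha = 0.05,
                       cutoff = 0.091, direction = "low") {
  if (inherits(models, "prs_model")) models <- list(models)
  strata_levels <- if (is.null(strata)) NA_character_ else
    sort(unique(cohort[[strata]]))
  rows <- list()
  for (sl in strata_levels) {
    sub <- if (is.na(sl)) cohort else cohort[cohort[[strata]] == sl, ,
                                             drop = FALSE]
    for (bm in biomarkers) {
      for (mod in models) {
        covs <- covariates %||% default_covariates(cohort, mod$apoe_included)
        if (adjust_for_mediator) covs <- union(covs, "ab_status")
        score <- mod$score[match(sub$individual_id, names(mod$score))]
        covd <- sub[, covs, drop = FALSE]
        n_ok <- sum(stats::complete.cases(covd) & !is.na(score))
        if (n_ok < length(covs) + 4) {
          rows[[length(rows) + 1]] <-
            new_assoc_result(mod$label, bm, NA, NA, NA, NA, n_ok,
                             if (bm == "ab_ratio") "logistic" else "linear",
                             adjust_for_mediator, as.character(sl),
                             "skipped: insufficient n")
          next
        }
        res <- tryCatch({
          if (bm == "ab_ratio") {
            y <- dichotomize_ab(sub$ab42, sub$ab40, cutoff, direction)
            logistic_assoc(y, score, covd, model = mod$label, biomarker = bm,
                           mediator_adjusted = adjust_for_mediator)
          } else {
            y <- inverse_normal_transform(sub[[bm]])
            linear_assoc(y, score, covd, model = mod$label, biomarker = bm,
                         mediator_adjusted = adjust_for_mediator)
          }
        }, error = function(e) {
          new_assoc_result(mod$label, bm, NA, NA, NA, NA, n_ok,
                           if (bm == "ab_ratio") "logistic" else "linear",
                           adjust_for_mediator, as.character(sl),
                           paste("skipped:", conditionMessage(e)))
        })
        res$stratum <- as.character(sl)
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  # Bonferroni within each biomarker (x stratum) family: m = models tested
  fam <- paste(out$biomarker, ifelse(is.na(out$stratum), "", out$stratum),
               out$mediator_adjusted)
  for (f in unique(fam)) {
    w <- fam == f & out$status == "ok"
    out$bonferroni_sig[w] <- out$p[w] < alpha / sum(w)
  }
  rownames(out) <- NULL
  out
}
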