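#' Bootstrap mediation of a PRS effect through a binary mediator
#'
#' Difference-of-coefficients mediation with a nonparametric bootstrap:
#' the total effect `c` is the exposure coefficient from OLS of the outcome
#' on exposure + covariates; the direct effect `c'` and the mediator path
#' `b` come from the same model with the mediator added; the exposure ->
#' mediator path `a` is a linear-probability OLS (standardized-coefficient
#' presentation across paths). The indirect effect is `c - c'` and the
#' proportion mediated `(c - c') / c`. Individuals (paired rows) are
#' resampled `n_boot` times; the indirect-effect CI is the percentile
#' interval of the resampled `c - c'`, and the two-sided bootstrap p-value
#' is `2 * min(frac <= 0, frac >= 0)`.
#'
#' The proportion mediated is reported as `NA` when `|c| < prop_guard *
#' SE(c)`: when the total effect is indistinguishable from noise the ratio
#' is uninterpretable.
#'
#' @param exposure numeric vector (typically a standardized PRS) or a
#'   `prs_model`.
#' @param mediator binary 0/1 vector; both classes must be present.
#' @param outcome numeric vector (typically an inverse-normal transformed
#'   biomarker).
#' @param covariates data.frame/matrix of covariates, or `NULL`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap stream.
#' @param prop_guard guard multiplier for the proportion-mediated report.
#' @param ci_level percentile-interval coverage (default 0.95).
#' @return an object of class `prs_mediation` with paths `a`, `b`, `c`,
#'   `c_prime` (each with estimate, se, p), `indirect`, `proportion_mediated`,
#'   `ci` (percentile bounds), `p_boot`, `boot` (resampled indirect effects),
#'   `n`, `n_boot`, `seed`.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000, seed = 1L, prop_guard = 10,
                    ci_level = 0.95) {
  if (inherits(exposure, "prs_model")) exposure <- exposure$score
  if (n_boot < 1) stop("n_boot must be >= 1")
  cov_m <- if (is.null(covariates))
    matrix(numeric(0), nrow = length(outcome), ncol = 0)
  else as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(cbind(exposure, mediator, outcome, cov_m))
  exposure <- exposure[ok]; mediator <- mediator[ok]
  outcome <- outcome[ok]
  cov_m <- cov_m[ok, , drop = FALSE]
  if (length(unique(mediator)) < 2)
    stop("mediator must include both classes")
  n <- length(outcome)
  Xc <- cbind(1, exposure, cov_m)                 # outcome ~ exposure
  Xcp <- cbind(1, exposure, mediator, cov_m)      # outcome ~ exposure + mediator
  fit_c <- ols_term(Xc, outcome, 2)
  fit_cp <- ols_term(Xcp, outcome, 2)
  fit_b <- ols_term(Xcp, outcome, 3)
  fit_a <- ols_term(Xc, mediator, 2)
  c_hat <- fit_c$beta; cp_hat <- fit_cp$beta
  indirect <- c_hat - cp_hat
  prop <- if (abs(c_hat) < prop_guard * fit_c$se) NA_real_ else
    indirect / c_hat
  set.seed(seed)
  boot <- numeric(n_boot)
  qrfit <- stats::.lm.fit
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- outcome[idx]
    cb <- qrfit(Xc[idx, , drop = FALSE], yb)$coefficients[2]
    cpb <- qrfit(Xcp[idx, , drop = FALSE], yb)$coefficients[2]
    boot[r] <- cb - cpb
  }
  alpha2 <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(boot, c(alpha2, 1 - alpha2), type = 7))
  p_boot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  structure(list(a = fit_a, b = fit_b, c = fit_c, c_prime = fit_cp,
                 indirect = indirect, proportion_mediated = prop,
                 ci = ci, ci_level = ci_level, p_boot = p_boot,
                 boot = boot, n = n, n_boot = n_boot, seed = seed),
            class = "prs_mediation")
}

# OLS beta/se/p for one design column.
ols_term <- function(X, y, j) {
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  se <- sqrt(diag(chol2inv(qr.R(fit$qr))) * rss / max(df, 1))
  beta <- unname(fit$coefficients[j])
  tval <- beta / se[j]
  list(beta = beta, se = unname(se[j]),
       p = unname(2 * stats::pt(-abs(tval), df)))
}

#' @export
print.prs_mediation <- function(x, digits = 3, ...) {
  cat("Bootstrap mediation (difference of coefficients), n =", x$n,
      ", bootstraps =", x$n_boot, "\n")
  paths <- rbind(a = unlist(x$a), b = unlist(x$b), c = unlist(x$c),
                 `c'` = unlist(x$c_prime))
  print(round(paths, digits))
  cat(sprintf("indirect (c - c') = %.*f, %g%% percentile CI [%.*f, %.*f], bootstrap p = %.3g\n",
              digits, x$indirect, 100 * x$ci_level, digits, x$ci[1],
              digits, x$ci[2], x$p_boot))
  if (is.na(x$proportion_mediated)) {
    cat("proportion mediated: undefined (total effect below guard)\n")
  } else {
    cat(sprintf("proportion mediated = %.1f%%\n",
                100 * x$proportion_mediated))
  }
  invisible(x)
}

#' @export
coef.prs_mediation <- function(object, ...) {
  c(a = object$a$beta, b = object$b$beta, c = object$c$beta,
    c_prime = object$c_prime$beta, indirect = object$indirect)
}

#' @export
confint.prs_mediation <- function(object, parm = "indirect", level, ...) {
  matrix(object$ci, nrow = 1,
         dimnames = list("indirect",
                         paste0(100 * c((1 - object$ci_level) / 2,
                                        1 - (1 - object$ci_level) / 2), "%")))
}

#' @export
summary.prs_mediation <- function(object, ...) {
  out <- data.frame(path = c("a", "b", "c", "c_prime"),
                    beta = c(object$a$beta, object$b$beta, object$c$beta,
                             object$c_prime$beta),
                    se = c(object$a$se, object$b$se, object$c$se,
                           object$c_prime$se),
                    p = c(object$a$p, object$b$p, object$c$p,
                          object$c_prime$p))
  attr(out, "indirect") <- object$indirect
  attr(out, "proportion_mediated") <- object$proportion_mediated
  attr(out, "ci") <- object$ci
  attr(out, "p_boot") <- object$p_boot
  out
}

#' Serialize a mediation result to a JSON-ready list / TSV row
#' @param x a `prs_mediation`.
#' @return named list of scalar fields (bootstrap draws omitted).
#' @export
mediation_record <- function(x) {
  stopifnot(inherits(x, "prs_mediation"))
  list(a = x$a$beta, b = x$b$beta, c = x$c$beta, c_prime = x$c_prime$beta,
       indirect = x$indirect, proportion_mediated = x$proportion_mediated,
       ci_lower = x$ci[1], ci_upper = x$ci[2], p_boot = x$p_boot,
       n = x$n, n_boot = x$n_boot, seed = x$seed)
}
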