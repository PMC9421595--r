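test_that("inverse normal transform maps ranks to Blom quantiles", {
  out <- inverse_normal_transform(c(5, 1, 9))
  expect_equal(out[1], 0)
  expect_equal(out[3], qnorm(2.625 / 3.25))
  expect_equal(out[2], -qnorm(2.625 / 3.25))
  x <- sort(rnorm(50))
  y <- inverse_normal_transform(x)
  expect_true(all(diff(y) > 0))                 # monotone
  expect_lt(abs(mean(y)), 1e-10)
  expect_equal(rank(y), rank(x))                # rank-preserving
})

test_that("inverse normal transform handles ties and missing values", {
  v <- c(3, 1, 3, NA, 2)
  out <- inverse_normal_transform(v)
  expect_true(is.na(out[4]))
  expect_equal(out[1], out[3])                  # average ranks for ties
  expect_error(inverse_normal_transform(c(2, 2, 2)), "distinct")
})

test_that("linear association recovers exact relations and matches OLS oracle", {
  set.seed(5)
  prs <- rnorm(30)
  res <- linear_assoc(2 * prs, prs)
  expect_equal(res$beta, 2, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)

  # 6-point worked example against the normal-equations oracle
  y <- c(1.2, 0.5, -0.3, 2.2, 1.1, -0.7)
  x <- c(0.4, -0.1, -1.2, 1.5, 0.8, -0.9)
  z <- c(1, 0, 1, 0, 1, 0)
  res <- linear_assoc(y, x, data.frame(z = z))
  oracle <- ols_oracle(cbind(1, x, z), y)
  expect_equal(res$beta, unname(oracle$beta[2]), tolerance = 1e-10)
  expect_equal(res$se, unname(oracle$se[2]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle$p[2]), tolerance = 1e-10)
  expect_equal(res$n, 6)
})

test_that("linear association matches the oracle across random designs", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(12:60, 1)
    x <- rnorm(n)
    covs <- matrix(rnorm(n * 2), ncol = 2,
                   dimnames = list(NULL, c("c1", "c2")))
    y <- 0.3 * x + covs %*% c(0.5, -0.2) + rnorm(n)
    res <- linear_assoc(drop(y), x, covs)
    oracle <- ols_oracle(cbind(1, x, covs), drop(y))
    expect_equal(res$beta, unname(oracle$beta[2]), tolerance = 1e-10)
    expect_equal(res$p, unname(oracle$p[2]), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  x <- rnorm(20)
  expect_error(linear_assoc(rnorm(20), x, data.frame(dup = x)),
               "collinear.*dup")
})

test_that("logistic association equals the contingency-table log odds ratio", {
  set.seed(7)
  x <- rbinom(400, 1, 0.5)
  y <- rbinom(400, 1, plogis(-0.3 + 0.8 * x))
  res <- logistic_assoc(y, x)
  tab <- table(x, y)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(res$beta, lor, tolerance = 1e-6)
  expect_equal(res$family, "logistic")
})

test_that("logistic association rejects degenerate outcomes and separation", {
  x <- rnorm(50)
  expect_error(logistic_assoc(rep(1, 50), x), "both classes")
  y <- as.integer(x > 0)   # perfectly separated
  expect_error(logistic_assoc(y, x), "separation")
})

test_that("logistic p-values are calibrated under permutation", {
  set.seed(8)
  y <- rbinom(300, 1, 0.4)
  p <- vapply(1:200, function(i) {
    logistic_assoc(y, sample(rnorm(300)))$p
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("amyloid dichotomization respects cutoff, direction and validity", {
  expect_equal(dichotomize_ab(45, 1000, 0.091), 1L)       # ratio 0.045
  expect_equal(dichotomize_ab(91, 1000, 0.091), 0L)       # exactly at cutoff
  expect_equal(dichotomize_ab(c(100, 95), c(1000, 1000), 0.091), c(0L, 0L))
  expect_equal(dichotomize_ab(45, 1000, 0.091, direction = "high"), 0L)
  expect_equal(dichotomize_ab(100, 1000, 0.091, direction = "high"), 1L)
  expect_error(dichotomize_ab(45, 0, 0.091), "positive")
})

test_that("scan applies Bonferroni within biomarker families", {
  set.seed(9)
  ids <- sprintf("rs%05d", 1:40)
  cc <- causal_config(independent_set = ids[1:10], w_ind = 0.15)
  sc <- simulate_cohort(500, 40, cc, seed = 9)
  models <- suppressWarnings(threshold_series(sc$stats, sc$panel,
                                              exclude_apoe = FALSE))
  res <- assoc_scan(models, sc$cohort, biomarkers = "ptau181",
                    covariates = c("age", "sex"))
  expect_equal(nrow(res), 7)
  ok <- res$status == "ok"
  expect_equal(res$bonferroni_sig[ok], res$p[ok] < 0.05 / sum(ok))
})

test_that("planted direct effects survive mediator adjustment in the scan", {
  set.seed(10)
  ids <- sprintf("rs%05d", 1:50)
  cc <- causal_config(dependent_set = ids[1:5], independent_set = ids[6:25])
  sc <- simulate_cohort(2000, 50, cc, seed = 10)
  co <- add_pcs(sc$cohort, sc$panel, 10)
  kept <- clump(sc$stats, sc$panel)
  w <- setNames(sc$stats$beta, sc$stats$id)[kept]
  model <- prs_from_weights(sc$panel, w, "PRS")
  unadj <- assoc_scan(model, co, biomarkers = "ptau181")
  adj <- assoc_scan(model, co, biomarkers = "ptau181",
                    adjust_for_mediator = TRUE)
  expect_gt(adj$beta / unadj$beta, 0.8)
  expect_lt(adj$p, 0.05)
})

test_that("stratified scans emit skipped rows when a stratum is too small", {
  set.seed(11)
  sc <- simulate_cohort(300, 10, null_config(), seed = 11)
  co <- sc$cohort
  co$dx_group <- c("AD", rep(c("CU", "MCI"), length.out = 299))
  model <- prs_from_weights(sc$panel,
                            setNames(sc$stats$beta, sc$stats$id), "PRS")
  res <- assoc_scan(model, co, biomarkers = "ptau181", strata = "dx_group",
                    covariates = c("age", "sex"))
  expect_equal(nrow(res), 3)
  ad <- res[res$stratum == "AD", ]
  expect_match(ad$status, "skipped")
  expect_true(all(res$status[res$stratum != "AD"] == "ok"))
})

test_that("null biomarkers rarely reach Bonferroni significance", {
  hits <- vapply(1:20, function(s) {
    sc <- simulate_cohort(250, 12, null_config(), seed = 1000 + s)
    models <- suppressWarnings(
      threshold_series(sc$stats, sc$panel, thresholds = c(0.5, 0.05, 5e-3),
                       exclude_apoe = FALSE))
    res <- assoc_scan(models, sc$cohort, biomarkers = "nfl",
                      covariates = c("age", "sex"))
    any(res$bonferroni_sig[res$status == "ok"])
  }, logical(1))
  expect_lte(sum(hits), 2)
})
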