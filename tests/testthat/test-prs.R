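test_that("region exclusion uses inclusive 1-based bounds", {
  d <- matrix(rbinom(40 * 4, 2, 0.3), ncol = 4)
  panel <- make_panel(d, chrom = c("19", "19", "19", "18"),
                      pos = c(44400000, 44399999, 46500000, 45000000))
  ss <- make_stats(panel, p = c(1e-4, 1e-4, 1e-4, 1e-4))
  out <- exclude_region(ss, apoe_region())
  expect_setequal(out$id, c("v2", "v4"))  # boundary variants removed
  expect_equal(out$id, c("v2", "v4"))     # order preserved
})

test_that("clumping keeps the most significant of a correlated pair", {
  set.seed(2)
  g <- rbinom(100, 2, 0.4)
  panel <- make_panel(cbind(g, g), pos = c(100000, 110000))
  ss <- make_stats(panel, p = c(1e-4, 1e-8))
  expect_equal(clump(ss, panel), "v2")
  ss2 <- make_stats(panel, p = c(1e-8, 1e-4))
  expect_equal(clump(ss2, panel), "v1")
})

test_that("variants on different chromosomes are never clumped together", {
  set.seed(3)
  g <- rbinom(50, 2, 0.4)
  panel <- make_panel(cbind(g, g, g), chrom = c("1", "2", "3"),
                      pos = c(1000, 1000, 1000))
  ss <- make_stats(panel, p = c(1e-8, 1e-6, 1e-4))
  expect_setequal(clump(ss, panel), c("v1", "v2", "v3"))
  expect_equal(clump(ss[0, ], panel), character(0))
})

test_that("clumping matches an independent greedy oracle on random panels", {
  for (s in 1:5) {
    set.seed(s)
    panel <- simulate_genotypes(300, 30, ld_block_size = 5, ld_rho = 0.7,
                                seed = s)
    ss <- make_stats(panel, p = runif(30, 1e-10, 1))
    mine <- clump(ss, panel, r2_max = 0.1, window_kb = 1000)
    oracle <- clump_oracle(ss, panel, r2_max = 0.1, window_kb = 1000)
    expect_equal(mine, oracle)
    # invariant: no retained same-chromosome pair in-window with r2 >= 0.1
    kept <- panel$variants[match(mine, panel$variants$id), ]
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        if (kept$chrom[i] == kept$chrom[j] &&
            abs(kept$pos[i] - kept$pos[j]) <= 1e6) {
          expect_lt(ld_r2(panel, kept$id[i], kept$id[j]), 0.1)
        }
      }
    }
  }
})

test_that("scores are exact weighted dosage sums", {
  panel <- make_panel(matrix(c(2, 1, 0, 1), nrow = 1), pos = 1:4)
  w <- c(v1 = 0.2, v2 = -0.1)
  expect_equal(unname(prs_score(panel, w)), 0.3)
  expect_equal(unname(prs_score(panel, c(v1 = 0, v2 = 0, v3 = 0))), 0)
  expect_error(prs_score(panel, c(nope = 1)), "absent from the panel")
})

test_that("missing dosages contribute their mean-imputed value", {
  # maf 0.25 from complete rows -> mean dosage 0.5 imputed for the NA
  g <- c(1, 1, 0, 0, NA)
  panel <- make_panel(matrix(g, ncol = 1))
  w <- c(v1 = 0.4)
  sc <- prs_score(panel, w)
  expect_equal(unname(sc[5]), 0.4 * 0.5)
  expect_equal(unname(sc[1]), 0.4)
})

test_that("allele harmonization reflects swapped panels and rejects mismatches", {
  g <- c(0, 1, 2, 2)
  panel_fwd <- make_panel(matrix(g, ncol = 1), a1 = "A", a2 = "G")
  panel_swp <- make_panel(matrix(2 - g, ncol = 1), a1 = "G", a2 = "A")
  ss <- make_stats(panel_fwd, p = 0.5, beta = 0.3)
  s1 <- prs_score(panel_fwd, ss)
  s2 <- prs_score(panel_swp, ss)
  expect_equal(unname(s1), unname(s2))
  panel_bad <- make_panel(matrix(g, ncol = 1), a1 = "A", a2 = "C")
  expect_error(prs_score(panel_bad, ss), "allele mismatch")
})

test_that("scores equal brute-force dot products on random panels", {
  set.seed(17)
  panel <- simulate_genotypes(80, 25, missing_rate = 0.03, seed = 17)
  w <- setNames(rnorm(25), panel$variants$id)
  sc <- prs_score(panel, w)
  g <- panel$dosage
  cm <- colMeans(g, na.rm = TRUE)
  for (j in 1:25) g[is.na(g[, j]), j] <- cm[j]
  brute <- as.vector(g %*% w)
  expect_equal(unname(sc), brute, tolerance = 1e-12)
})

test_that("threshold series is nested, counted correctly, and standardized", {
  set.seed(23)
  panel <- simulate_genotypes(400, 60, seed = 23)
  p <- 10^runif(60, -9, 0)
  ss <- make_stats(panel, p = p, beta = rnorm(60, 0, 0.1))
  thr <- c(0.05, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 5e-8)
  models <- threshold_series(ss, panel, exclude_apoe = FALSE)
  expect_length(models, 7)
  expect_equal(vapply(models, `[[`, 0, "threshold"), thr)
  kept <- clump(ss, panel)
  pk <- p[match(kept, ss$id)]
  for (i in seq_along(models)) {
    m <- models[[i]]
    expect_equal(length(m$variants), sum(pk <= thr[i]))  # counting oracle
    expect_true(all(ss$p[match(m$variants, ss$id)] <= thr[i]))
    if (i > 1) expect_true(all(m$variants %in% models[[i - 1]]$variants))
    if (length(m$variants)) {
      expect_lt(abs(mean(m$score)), 1e-10)
      expect_equal(sd(m$score), 1, tolerance = 1e-10)
    }
  }
})

test_that("a threshold retaining no variants yields a warned empty model", {
  set.seed(29)
  panel <- simulate_genotypes(100, 10, seed = 29)
  ss <- make_stats(panel, p = rep(0.5, 10))
  expect_warning(models <- threshold_series(ss, panel, thresholds = c(0.9, 1e-4),
                                            exclude_apoe = FALSE),
                 "retains no variants")
  expect_length(models[[2]]$variants, 0)
  expect_true(all(models[[2]]$score == 0))
})

test_that("thresholds must strictly decrease", {
  panel <- simulate_genotypes(50, 5, seed = 1)
  ss <- make_stats(panel, p = rep(0.01, 5))
  expect_error(threshold_series(ss, panel, thresholds = c(0.05, 0.05)),
               "strictly decreasing")
})
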