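# Shared small planted cohort for the decomposition unit tests.
dec_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ids <- sprintf("rs%05d", 1:30)
    cc <- causal_config(dependent_set = ids[1:5],
                        independent_set = ids[6:13],
                        w_dep = 0.3, w_ind = 0.25)
    sc <- simulate_cohort(1500, 30, cc, seed = 61)
    w <- setNames(sc$stats$beta, sc$stats$id)
    cache <<- list(sc = sc, w = w, ids = ids,
                   outcome = inverse_normal_transform(sc$cohort$ptau181),
                   mediator = sc$cohort$ab_status,
                   covs = basic_covariates(sc$cohort))
    cache
  }
})

test_that("removing a zero-weight variant leaves the mediator association unchanged", {
  f <- dec_fixture()
  w <- f$w
  w["rs00030"] <- 0
  rec <- loo_scan(w, f$sc$panel, f$mediator, f$covs)
  expect_equal(nrow(rec), 30)
  row <- rec[rec$id == "rs00030", ]
  expect_equal(row$p_loo, row$p_full, tolerance = 1e-12)
  expect_error(loo_scan(w[1], f$sc$panel, f$mediator, f$covs), "at least 2")
})

test_that("removing a strong mediator-path variant weakens the association most", {
  f <- dec_fixture()
  rec <- loo_scan(f$w, f$sc$panel, f$mediator, f$covs)
  worst <- rec$id[which.max(rec$p_loo)]
  expect_true(worst %in% f$ids[1:5])
  expect_true(all(rec$direction[rec$id %in% f$ids[1:5]] == "weakened"))
})

test_that("ranking orders by p with deterministic id tie-breaks", {
  rec <- data.frame(id = c("b", "a", "c"), p_loo = c(0.3, 0.01, 0.2))
  expect_equal(rank_variants(rec), c("a", "c", "b"))
  expect_equal(rank_variants(rec, "descending"), c("b", "c", "a"))
  ties <- data.frame(id = c("z", "m", "a"), p_loo = c(0.5, 0.5, 0.5))
  expect_equal(rank_variants(ties), c("a", "m", "z"))
  expect_equal(rank_variants(ties, "descending"), c("a", "m", "z"))
})

test_that("the nested profile ends at the full-PRS fit", {
  f <- dec_fixture()
  rec <- loo_scan(f$w, f$sc$panel, f$mediator, f$covs)
  ranked <- rank_variants(rec)
  prof <- nested_profile(ranked, f$w, f$sc$panel, f$outcome, f$mediator,
                         f$covs, n_boot_screen = 50, seed = 3)
  expect_equal(nrow(prof), 30)
  expect_equal(prof$k, 1:30)
  full <- linear_assoc(f$outcome, standardize(prs_score(f$sc$panel, f$w)),
                       f$covs)
  expect_equal(prof$beta_unadj[30], full$beta, tolerance = 1e-10)
  expect_equal(prof$p_unadj[30], full$p, tolerance = 1e-10)
  expect_true(all(prof$status == "ok"))
})

test_that("independent-candidate selection applies both screens", {
  ranked <- paste0("v", 1:4)
  prof <- data.frame(k = 1:4, variant_added = ranked,
                     beta_unadj = c(0.2, 0.25, 0.3, 0.3),
                     p_unadj = c(0.3, 0.01, 0.01, 0.001),
                     beta_adj = c(0.2, 0.22, 0.29, 0.2),
                     p_adj = c(0.3, 0.01, 0.02, 0.001),
                     p_med = c(0.8, 0.5, 0.2, 0.01),
                     status = "ok", stringsAsFactors = FALSE)
  attr(prof, "ranked_ids") <- ranked
  class(prof) <- c("nested_profile", "data.frame")
  sel <- select_independent(prof, alpha = 0.05)
  # k=1 fails the outcome screen; k=4 fails the mediation screen
  expect_equal(sel$candidate_ks, c(2, 3))
  expect_equal(sel$optimal_k, 3)        # |0.29 - 0.3| < |0.22 - 0.25|
  expect_equal(sel$optimal_subset, ranked[1:3])
  expect_equal(sel$candidate_union, ranked[1:3])

  all_mediated <- prof
  all_mediated$p_med <- 0.001
  sel2 <- select_independent(all_mediated)
  expect_length(sel2$candidate_ks, 0)
  expect_equal(sel2$optimal_subset, character(0))
})

test_that("the exclusive dependent subset is the complement of the candidate union", {
  w <- setNames(rep(0.1, 5), paste0("v", 1:5))
  out <- exclusive_dependent(w, c("v1", "v2"))
  expect_equal(out$ids, c("v3", "v4", "v5"))
  out2 <- exclusive_dependent(w, character(0))
  expect_equal(out2$ids, names(w))
  expect_warning(out3 <- exclusive_dependent(w, names(w)), "no dependent")
  expect_length(out3$ids, 0)
  expect_error(exclusive_dependent(w, "zzz"), "not subsets")
})

test_that("the joint two-PRS model is symmetric under argument swap", {
  f <- dec_fixture()
  ind <- f$ids[6:13]; dep <- f$ids[1:5]
  j1 <- joint_model(ind, dep, f$w, f$sc$panel, f$outcome, f$mediator, f$covs)
  j2 <- joint_model(dep, ind, f$w, f$sc$panel, f$outcome, f$mediator, f$covs)
  expect_equal(j1$beta[j1$subset == "independent" & !j1$mediator_adjusted],
               j2$beta[j2$subset == "dependent" & !j2$mediator_adjusted],
               tolerance = 1e-10)
  expect_error(joint_model(c("rs00001"), c("rs00001"), f$w, f$sc$panel,
                           f$outcome, f$mediator, f$covs), "disjoint")
  expect_error(joint_model(character(0), dep, f$w, f$sc$panel, f$outcome,
                           f$mediator, f$covs), "non-empty")
})

test_that("full decomposition output is internally consistent and deterministic", {
  f <- dec_fixture()
  model <- prs_from_weights(f$sc$panel, f$w, "PRSfull")
  dec <- decompose_prs(model, f$sc$panel, f$sc$cohort,
                       covariates = c("age", "sex", "education", "mmse",
                                      "apoe4_count", "apoe2_count"),
                       n_boot_screen = 50, n_boot = 100, seed = 17)
  expect_length(intersect(dec$independent_subset, dec$dependent_subset), 0)
  expect_true(all(c(dec$independent_subset, dec$dependent_subset) %in%
                    names(f$w)))
  expect_equal(sort(unique(c(dec$selection$candidate_union,
                             dec$dependent_subset))), sort(names(f$w)))
  dec2 <- decompose_prs(model, f$sc$panel, f$sc$cohort,
                        covariates = c("age", "sex", "education", "mmse",
                                       "apoe4_count", "apoe2_count"),
                        n_boot_screen = 50, n_boot = 100, seed = 17)
  expect_identical(dec$independent_subset, dec2$independent_subset)
  expect_identical(dec$profile$p_med, dec2$profile$p_med)
  expect_output(print(dec), "PRS decomposition")
})
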