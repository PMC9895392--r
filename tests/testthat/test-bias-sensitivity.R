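test_that("beggs_test matches the exhaustive pair-counting oracle (k = 6)", {
  eff <- make_effects(c(0.05, 0.62, 0.30, 0.95, 0.18, 0.44),
                      c(0.30, 0.08, 0.18, 0.04, 0.25, 0.12))
  # frozen from brute force over all C(6,2) pairs
  bt <- beggs_test(eff)
  expect_equal(bt$statistic, -15)
  expect_equal(bt$test_value, 2.6301420226, tolerance = 1e-9)
  expect_lt(abs(bt$p_value - 0.0085349204), 1e-9)
  raw <- beggs_test(eff, continuity_correction = FALSE)
  expect_equal(raw$test_value, 2.8180093099, tolerance = 1e-9)
  expect_lt(abs(raw$p_value - 0.0048322409), 1e-9)
})

test_that("beggs_test is maximal for a perfectly concordant construction", {
  # deviates and variances strictly increasing together: all 10 pairs agree
  eff <- make_effects(c(0, 1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(beggs_test(eff)$statistic, 10)
  expect_error(beggs_test(make_effects(c(0, 1), c(0.1, 0.2))),
               "at least 3")
})

test_that("beggs_test p is invariant under variance rescaling", {
  # scaling all variances is an order-preserving transform that rescales
  # the deviates uniformly, so the Kendall score is unchanged
  set.seed(88)
  for (i in 1:10) {
    eff <- random_effects(sample(4:12, 1))
    p0 <- beggs_test(eff)$p_value
    for (cc in c(0.2, 5, 100)) {
      scaled <- make_effects(eff$smd, cc * eff$variance)
      expect_equal(beggs_test(scaled)$p_value, p0)
    }
  }
})

test_that("eggers_test matches the closed-form OLS oracle (k = 5)", {
  se <- c(0.40, 0.25, 0.30, 0.15, 0.35)
  eff <- make_effects(c(0.10, 0.45, 0.30, 0.80, 0.25), se^2)
  et <- eggers_test(eff)
  expect_equal(et$statistic, -2.9311786395, tolerance = 1e-9)
  expect_equal(et$se, 0.2234507524, tolerance = 1e-9)
  expect_equal(et$test_value, -13.1177837102, tolerance = 1e-8)
  expect_equal(et$df, 3L)
  expect_lt(abs(et$p_value - 0.0009569238), 1e-9)
  expect_equal(et$slope, 1.2271187138, tolerance = 1e-9)
})

test_that("eggers_test is null-centered when effects do not depend on
           precision", {
  # symmetric effects around a common mean, precision independent of effect
  set.seed(512)
  theta <- 0.3 + rnorm(20, 0, 0.05)
  v <- runif(20, 0.02, 0.3)
  et <- eggers_test(make_effects(theta, v))
  expect_gt(et$p_value, 0.05)

  # identical true effects: intercept is 0 to numerical tolerance
  exact <- suppressWarnings(  # summary.lm flags the perfect fit
    eggers_test(make_effects(rep(0.42, 6), c(1:6) / 10)))
  expect_lt(abs(exact$statistic), 1e-10)

  expect_error(eggers_test(make_effects(1:5 / 10, rep(0.2, 5))), "singular")
  expect_error(eggers_test(make_effects(c(0, 1), c(0.1, 0.2))), "at least 3")
})

test_that("fixture strata show no publication bias (p > 0.05)", {
  for (args in list(c("mRNA", "late"), c("protein", "late"),
                    c("protein", "middle"))) {
    eff <- compute_effects(load_gdf15_fixture(args[1], args[2]))
    expect_gt(beggs_test(eff)$p_value, 0.05)
    expect_gt(eggers_test(eff)$p_value, 0.05)
  }
})

test_that("leave_one_out rows are identical to pooling the explicit subsets", {
  set.seed(7)
  eff <- random_effects(4)
  for (model in c("random", "fixed")) {
    loo <- leave_one_out(eff, model = model)
    expect_equal(nrow(loo), 4L)
    expect_equal(loo$omitted_study_id, eff$study_id)
    pool_fun <- if (model == "fixed") fixed_effect else dersimonian_laird
    for (i in 1:4) {
      direct <- pool_fun(eff[-i, ])
      expect_identical(attr(loo, "results")[[i]]$pooled, direct$pooled)
      expect_identical(attr(loo, "results")[[i]]$se, direct$se)
      expect_equal(loo$k[i], 3L)
    }
  }
})

test_that("leave_one_out reduces to the remaining study at k = 2", {
  eff <- make_effects(c(0.1, 0.9), c(0.04, 0.16))
  loo <- leave_one_out(eff)
  expect_equal(loo$pooled, rev(eff$smd))
  expect_equal(loo$ci_low, rev(eff$ci_low), tolerance = 1e-12)
  expect_error(leave_one_out(eff[1, ]), "at least 2")
})

test_that("leave_one_out on the mRNA-late stratum is directionally stable", {
  eff <- compute_effects(load_gdf15_fixture("mRNA", "late"))
  loo <- leave_one_out(eff)
  expect_equal(nrow(loo), 12L)
  # "basically stable": positive pooled direction in the large majority
  expect_gte(sum(loo$pooled > 0), 10L)
})

test_that("restricted_analysis reproduces the published sensitivity results", {
  r1 <- restricted_analysis(load_gdf15_fixture("mRNA", "late"))
  expect_equal(round(r1$pooled, 2), 0.61)
  expect_equal(r1$k, 5L)
  r2 <- restricted_analysis(load_gdf15_fixture("protein", "late"))
  expect_equal(round(r2$pooled, 2), 0.57)
  r3 <- restricted_analysis(load_gdf15_fixture("protein", "middle"))
  expect_equal(round(r3$pooled, 2), 0.39)

  none <- study_collection(make_study_df(2))
  expect_error(restricted_analysis(none), "no studies left")
})
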