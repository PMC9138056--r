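# Closed-form incorporation models and derived turnover algebra.

test_that("growth-based model evaluates, respects limits and rejects bad WR", {
  # pure dilution halves the offset when biomass doubles
  expect_equal(predict_model_g(2, 0, 1, -1), 0.5)
  # equilibrium limit: offset vanishes as WR grows
  expect_equal(predict_model_g(1e8, -16.3, -4.4, -1.474), -16.3,
               tolerance = 1e-6)
  # direct evaluation frozen from scalar arithmetic
  expect_equal(predict_model_g(1.6, -16.3, -4.4, -1.474), -18.5008,
               tolerance = 1e-4)
  expect_error(predict_model_g(0, -16, -4, -1.4), "positive")
  expect_error(predict_model_g(-2, -16, -4, -1.4), "positive")
})

test_that("dilution-model equivalence: c = -1 is delta_eq + a/WR", {
  wr <- seq(1, 30, length.out = 23)
  expect_equal(predict_model_g(wr, -16.3, -4.4, -1), -16.3 + (-4.4) / wr)
})

test_that("time-based model evaluates, hits t = 0 exactly, rejects t < 0", {
  # at the switch the value is delta_i = delta_eq + a
  expect_equal(predict_model_d(0, 14.2, -4.4, 0.041, 0.062), 14.2 - 4.4)
  # one half-life at rate ln 2
  expect_equal(predict_model_d(1, 0, 8, log(2), 0), 4)
  # offset halves at the 50% turnover time
  expect_equal(predict_model_d(6.64, -15.6, -3.0, 0.035, 0.0694), -17.10,
               tolerance = 1e-3)
  expect_error(predict_model_d(-1, 0, 1, 0.1, 0.1), ">= 0")
})

test_that("half the offset remains exactly at the model-D half-life", {
  for (m in c(0, 0.02, 0.05)) {
    for (k in c(0.03, 0.062, 0.0694)) {
      d50 <- turnover_days(m, k, 50)
      expect_equal(predict_model_d(d50, -15.6, -3.0, m, k) - (-15.6), -3.0 / 2)
    }
  }
})

test_that("growth rate from endpoint weights matches hand calculation", {
  expect_equal(growth_rate_k(0.80, 22.78, 54), log(28.475) / 54)
  expect_equal(round(growth_rate_k(0.80, 22.78, 54), 4), 0.0620)
  expect_equal(round(growth_rate_k(2.20, 65.85, 49), 4), 0.0694)
  expect_equal(growth_rate_k(5, 5, 10), 0)
  expect_error(growth_rate_k(1, 2, 0), "positive")
  expect_error(growth_rate_k(-1, 2, 5), "positive")
})

test_that("fold-mass turnover matches reference values and its invariants", {
  expect_equal(round(turnover_weight_fold(-1.474, 50), 1), 1.6)
  expect_equal(round(turnover_weight_fold(-0.844, 95), 1), 34.8)
  expect_identical(turnover_weight_fold(-1, 50), 2)
  # strictly decreasing in |c| at fixed alpha; increasing in alpha
  cs <- -c(0.5, 0.8, 1, 1.5, 3, 9)
  expect_true(all(diff(sapply(cs, turnover_weight_fold, alpha = 50)) < 0))
  expect_true(all(diff(turnover_weight_fold(-1.2, c(10, 50, 90, 99))) > 0))
  expect_error(turnover_weight_fold(0.5, 50), "negative")
  expect_error(turnover_weight_fold(-1, 100), "between")
  expect_error(turnover_weight_fold(-1, 0), "between")
})

test_that("chronological turnover is positive days with the fixed 95/50 ratio", {
  expect_equal(round(turnover_days(0.035, 0.0694, 50), 1), 6.6)
  expect_equal(round(turnover_days(0.040, 0.0620, 95), 1), 29.4)
  expect_equal(turnover_days(0, log(2), 50), 1)
  # D95/D50 = ln .05 / ln .5 for any rate: equilibrium after 4-5 half-lives
  for (mk in list(c(0, 0.1), c(0.04, 0.062), c(0.3, 0.01))) {
    r <- turnover_days(mk[1], mk[2], 95) / turnover_days(mk[1], mk[2], 50)
    expect_equal(r, log(0.05) / log(0.5))
  }
  expect_error(turnover_days(-0.1, 0.05, 50), "positive")
})

test_that("partition clips negative metabolism and always sums to one", {
  p <- partition_turnover(1.6)
  expect_equal(p[["p_m"]], 0.25, tolerance = 2e-3)
  expect_equal(unname(partition_turnover(2.0)), c(1, 0))
  expect_equal(unname(partition_turnover(2.5)), c(1, 0))  # clipped
  for (g in c(1, 1.2, 1.7, 2, 3, 10))
    expect_equal(sum(partition_turnover(g)), 1)
  # independent identity: p_m = 1 - p_g
  expect_equal(partition_turnover(1.6)[["p_m"]],
               1 - partition_turnover(1.6)[["p_g"]])
  expect_error(partition_turnover(0.9), ">= 1")
})

test_that("discrimination factor is the equilibrium-diet difference", {
  expect_equal(round(discrimination_factor(-16.3, -18.03), 1), 1.7)
  expect_equal(round(discrimination_factor(14.6, 12.27), 1), 2.3)
  expect_equal(discrimination_factor(3.3, 3.3), 0)
  # antisymmetric
  expect_equal(discrimination_factor(-15.7, -18.03),
               -discrimination_factor(-18.03, -15.7))
  expect_error(discrimination_factor(14.6, -18.0, isotope = "d15N",
                                     diet_isotope = "d13C"), "mismatch")
})

test_that("R-squared is 1 for perfect fit, 0 for the mean, errors on flat data", {
  y <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(goodness_of_fit(y, y), 1)
  expect_equal(goodness_of_fit(y, rep(mean(y), 4)), 0)
  expect_error(goodness_of_fit(rep(2, 4), c(1, 2, 3, 4)), "zero variance")
})

test_that("implausible delta values are flagged, not rejected", {
  expect_equal(flag_implausible_delta(c(-70, -20, 5, 20), "d13C"),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(flag_implausible_delta(c(-30, 12), "d15N"), c(TRUE, FALSE))
})
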