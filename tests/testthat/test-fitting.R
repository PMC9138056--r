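# Nonlinear least-squares estimation of both incorporation models.

test_that("noise-free data are recovered to optimizer tolerance", {
  g <- noise_free_g(-16.3, -4.4, -1.474)
  fg <- fit_model_g(g$wr, g$delta)
  expect_true(fg$converged)
  expect_equal(unname(coef(fg)), c(-16.3, -4.4, -1.474), tolerance = 1e-6)
  expect_equal(fg$r2, 1, tolerance = 1e-9)

  d <- noise_free_d(14.6, -4.0, 0.030, k = 0.0694)
  fd <- fit_model_d(d$t, d$delta, k = 0.0694)
  expect_true(fd$converged)
  expect_equal(unname(coef(fd)), c(14.6, -4.0, 0.030), tolerance = 1e-6)
  expect_equal(fd$r2, 1, tolerance = 1e-9)
})

test_that("fitting the pure dilution process returns c within CI of -1", {
  set.seed(7)
  g <- noise_free_g(-16.3, -4.4, -1)
  fg <- fit_model_g(g$wr, g$delta + rnorm(7, 0, 0.15))
  ci <- confint(fg)["c", ]
  expect_true(ci[1] <= -1 && -1 <= ci[2])
})

test_that("fits are invariant to observation order and replicate relabeling", {
  set.seed(11)
  g <- noise_free_g(-16.3, -4.4, -1.474)
  delta <- g$delta + rnorm(7, 0, 0.15)
  f1 <- fit_model_g(g$wr, delta)
  perm <- sample(7)
  f2 <- fit_model_g(g$wr[perm], delta[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})

test_that("mean estimates over 500 noisy fits track the truth", {
  # noise on two-tank day means: 0.15 / sqrt(2) permil
  set.seed(101)
  t <- days_since_switch_a6
  k <- 0.0694
  truth <- c(delta_eq = 14.6, a = -6.9, m = 0.030)
  est <- t(replicate(500, {
    delta <- predict_model_d(t, truth[1], truth[2], truth[3], k) +
      rnorm(7, 0, 0.15 / sqrt(2))
    coef(fit_model_d(t, delta, k = k))
  }))
  bias <- colMeans(est) - truth
  mcse <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(bias[["delta_eq"]]), 2 * mcse[["delta_eq"]])
  expect_lt(abs(bias[["a"]]), 2 * mcse[["a"]])
  # m is constrained to m >= 0 (bounded sampling distribution): median-centred
  expect_equal(median(est[, "m"]), truth[["m"]], tolerance = 0.005)
  expect_true(all(est[, "m"] >= 0))
})

test_that("boundary truth m = 0 yields non-negative estimates with median near 0", {
  set.seed(23)
  t <- days_since_switch_a6
  est_m <- replicate(200, {
    delta <- predict_model_d(t, -16.2, -4.4, 0, 0.0620) +
      rnorm(7, 0, 0.15 / sqrt(2))
    coef(fit_model_d(t, delta, k = 0.0620))[["m"]]
  })
  expect_true(all(est_m >= 0))
  expect_lt(median(est_m), 0.01)
})

test_that("standard errors shrink as 1/sqrt(n) under design replication", {
  set.seed(31)
  t <- days_since_switch_a6
  mean_se <- function(fold, nrep = 40) {
    tt <- rep(t, fold)
    mean(replicate(nrep, {
      delta <- predict_model_d(tt, 14.6, -6.9, 0.030, 0.0694) +
        rnorm(length(tt), 0, 0.15)
      fit_model_d(tt, delta, k = 0.0694)$se[["delta_eq"]]
    }))
  }
  s1 <- mean_se(1); s2 <- mean_se(2); s4 <- mean_se(4)
  expect_equal(s2 / s1, 1 / sqrt(2), tolerance = 0.15)
  expect_equal(s4 / s1, 1 / 2, tolerance = 0.15)
})

test_that("perturbing the fixed k shifts the fitted m by -epsilon", {
  d <- noise_free_d(14.6, -4.0, 0.030, k = 0.0694)
  m0 <- coef(fit_model_d(d$t, d$delta, k = 0.0694))[["m"]]
  eps <- 0.004
  m1 <- coef(fit_model_d(d$t, d$delta, k = 0.0694 + eps))[["m"]]
  expect_equal(m1 - m0, -eps, tolerance = 1e-6)
})

test_that("time origin does not matter: shifted t changes only a", {
  d <- noise_free_d(14.6, -4.0, 0.030, k = 0.0694)
  f0 <- fit_model_d(d$t, d$delta, k = 0.0694)
  f1 <- fit_model_d(d$t + 11, d$delta, k = 0.0694)
  expect_equal(coef(f1)[["delta_eq"]], coef(f0)[["delta_eq"]],
               tolerance = 1e-6)
  expect_equal(coef(f1)[["m"]], coef(f0)[["m"]], tolerance = 1e-6)
  expect_equal(coef(f1)[["a"]],
               coef(f0)[["a"]] * exp((0.030 + 0.0694) * 11),
               tolerance = 1e-4)
})

test_that("synthetic reconstruction at the study design keeps high R2", {
  set.seed(43)
  d <- noise_free_d(14.2, -4.4, 0.041, k = 0.0620)  # A6 d15N-like
  r2 <- replicate(20, {
    fit_model_d(d$t, d$delta + rnorm(7, 0, 0.15 / sqrt(2)), k = 0.0620)$r2
  })
  expect_true(all(r2 >= 0.9))
})

test_that("degenerate and invalid inputs are flagged, not thrown", {
  f <- fit_model_g(c(1, 2, 4, 8), rep(5, 4))
  expect_false(f$converged)
  expect_match(f$flags, "degenerate")
  expect_equal(coef(f)[["a"]], 0)
  expect_error(fit_model_g(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_model_g(c(0.5, 2, 3, 4), c(1, 2, 3, 4)), ">= 1")
  expect_error(fit_model_d(c(-1, 2, 3, 4), c(1, 2, 3, 4), k = 0.05), ">= 0")
})

test_that("incorp_fit methods behave like a standard model object", {
  set.seed(5)
  g <- noise_free_g(-16.3, -4.4, -1.474)
  f <- fit_model_g(g$wr, g$delta + rnorm(7, 0, 0.1))
  expect_s3_class(f, "incorp_fit")
  expect_named(coef(f), c("delta_eq", "a", "c"))
  expect_equal(dim(vcov(f)), c(3, 3))
  expect_equal(fitted(f) + residuals(f), f$data$delta)
  expect_equal(predict(f), fitted(f))
  expect_equal(length(predict(f, c(1, 2, 5))), 3)
  expect_output(print(f), "incorporation model G")
  s <- summary(f)
  expect_output(print(s), "R2")
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(7, 3))
  tn <- turnover(f)
  expect_named(tn, c("g50", "g95"))
  expect_true(tn[["g95"]] > tn[["g50"]])
  p <- partition(f)
  expect_equal(sum(p), 1)
  expect_equal(discrimination(f, -18.03),
               coef(f)[["delta_eq"]] - (-18.03))
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(f))
})
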