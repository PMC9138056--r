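# Lipid normalization, weight ratios and growth rates.

test_that("lipid normalization is multiplicative and taxon/isotope specific", {
  expect_equal(lipid_normalize(-20.0, "seahorse", "d13C"), -18.06)
  expect_equal(lipid_normalize(5.0, "copepod", "d15N"), 6.85)
  f1 <- lipid_factors(); f1$f_d13C[f1$taxon == "seahorse"] <- 1
  expect_equal(lipid_normalize(10.0, "seahorse", "d13C", f1), 10.0)
  expect_error(lipid_normalize(1, "squid", "d13C"), "squid")
  # linear in the raw value under the multiplicative convention
  x <- 3.1; y <- -7.4
  expect_equal(lipid_normalize(x + y, "artemia", "d15N"),
               lipid_normalize(x, "artemia", "d15N") +
                 lipid_normalize(y, "artemia", "d15N"))
})

test_that("C:N trigger is strict at 3.56", {
  expect_true(needs_lipid_correction(5.75))
  expect_false(needs_lipid_correction(3.56))
  expect_false(needs_lipid_correction(2.85))
  expect_error(needs_lipid_correction(-1), "positive")
})

test_that("normalize_observations corrects only lipid-rich rows", {
  obs <- data.frame(diet_group = "A6", replicate = 1, day = c(6, 60),
                    dry_weight_mg = c(0.8, 22.78),
                    d13C = c(-20, -15), d15N = c(8, 15), C_N = c(5.75, 2.85))
  out <- normalize_observations(obs)
  expect_equal(out$lipid_normalized, c(TRUE, FALSE))
  expect_equal(out$d13C, c(-20 * 0.903, -15))
  expect_equal(out$d15N, c(8 * 1.019, 15))
})

test_that("weight ratios anchor at the switch day and require it", {
  w <- hreidi_weights()
  a6 <- data.frame(day = w$day[w$diet_group == "A6"],
                   dry_weight_mg = w$dw_mg[w$diet_group == "A6"])
  wr <- weight_ratios(a6, switch_day = 6)
  expect_equal(wr$w_r[wr$day == 6], 1)
  expect_equal(wr$w_r[wr$day == 60], 22.78 / 0.80)
  a11 <- data.frame(day = w$day[w$diet_group == "A11"],
                    dry_weight_mg = w$dw_mg[w$diet_group == "A11"])
  expect_equal(round(weight_ratios(a11, 11)$w_r[6], 2), 29.93)
  expect_true(all(weight_ratios(a11, 11)$w_r >= 1))
  expect_error(weight_ratios(a6, switch_day = 7), "switch day")
})

test_that("replicate growth rate recovers k exactly on exponential series", {
  for (k in c(0.02, 0.0620, 0.11)) {
    s <- exp_series(k = k)
    expect_equal(replicate_growth_rate(s, 6, 60), k)
    expect_equal(replicate_growth_rate(s, 6, 60, method = "regression"), k)
  }
  flat <- data.frame(day = c(6, 60), dry_weight_mg = c(5, 5))
  expect_equal(replicate_growth_rate(flat, 6, 60), 0)
  expect_error(replicate_growth_rate(exp_series(), 6, 61), "endpoint")
})

test_that("group growth rates from reference endpoint weights", {
  w <- hreidi_weights()
  a6 <- data.frame(day = w$day[w$diet_group == "A6"],
                   dry_weight_mg = w$dw_mg[w$diet_group == "A6"])
  a11 <- data.frame(day = w$day[w$diet_group == "A11"],
                    dry_weight_mg = w$dw_mg[w$diet_group == "A11"])
  expect_equal(round(replicate_growth_rate(a6, 6, 60), 4), 0.0620)
  expect_equal(round(replicate_growth_rate(a11, 11, 60), 4), 0.0694)
})

test_that("observation tables round-trip through CSV with validation", {
  exp <- simulate_experiment(default_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(exp$observations, path)
  back <- read_observations(path)
  expect_equal(back$d13C, exp$observations$d13C, tolerance = 1e-12)
  expect_equal(back$diet_group, exp$observations$diet_group)
  # missing column is a schema error
  bad <- exp$observations; bad$C_N <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_observations(path2), "C_N")
  # implausible values are flagged with a warning, not dropped
  odd <- exp$observations; odd$d13C[1] <- -99
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(odd, path3, row.names = FALSE)
  expect_warning(x <- read_observations(path3), "plausible")
  expect_equal(nrow(x), nrow(odd))
})

test_that("replicate means average tanks per diet and day", {
  obs <- rbind(
    data.frame(diet_group = "A6", replicate = 1, day = c(6, 11),
               dry_weight_mg = c(0.8, 1.2), d13C = c(-20, -19),
               d15N = c(8, 9), C_N = 3),
    data.frame(diet_group = "A6", replicate = 2, day = c(6, 11),
               dry_weight_mg = c(0.9, 1.4), d13C = c(-21, -18),
               d15N = c(9, 10), C_N = 3))
  m <- replicate_means(obs)
  expect_equal(nrow(m), 2)
  expect_equal(m$d13C, c(-20.5, -18.5))
  expect_equal(m$dry_weight_mg, c(0.85, 1.3))
})
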