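# Reference values from the 60-day Hippocampus reidi diet-switch rearing
# trial (diets A6 and A11, copepods -> Artemia nauplii) that this package
# was developed around. These printed group-level summaries are the inputs
# for the reproduction utilities and the synthetic generator defaults.

#' Reference dry weights and condition of H. reidi juveniles
#'
#' Group means (two tanks per diet) of survival, dry weight, standard
#' length and C:N ratio at each sampling day for the two feeding schedules:
#' A6 (Artemia from day 6) and A11 (Artemia from day 11). Days are DAR
#' (days after the male's pouch release).
#'
#' @return data.frame with columns `diet_group`, `day`, `survival_pct`,
#'   `dw_mg`, `dw_sd`, `sl_mm`, `sl_sd`, `c_n`, `c_n_sd`.
#' @examples
#' w <- hreidi_weights()
#' subset(w, diet_group == "A6" & day %in% c(6, 60))
#' @export
hreidi_weights <- function() {
  data.frame(
    diet_group = c(rep("A6", 7), rep("A11", 6)),
    day = c(6, 11, 18, 25, 32, 46, 60, 11, 18, 25, 32, 46, 60),
    survival_pct = c(100, 98.8, 90.4, 75.7, 70.9, 49.2, 47.9,
                     98.8, 95.2, 85.7, 85.4, 84.5, 77.4),
    dw_mg = c(0.80, 1.30, 3.33, 9.28, 10.50, 15.61, 22.78,
              2.20, 3.53, 10.63, 17.38, 22.85, 65.85),
    dw_sd = c(0.02, 0.39, 0.07, 2.30, 1.66, 4.17, 3.11,
              0.14, 0.85, 0.04, 6.29, 2.58, 7.41),
    sl_mm = c(12.33, 15.95, 20.19, 26.41, 29.32, 31.81, 35.01,
              18.15, 22.05, 26.74, 33.82, 36.94, 51.21),
    sl_sd = c(0.32, 2.52, 0.10, 4.12, 2.34, 5.07, 1.80,
              0.35, 2.39, 0.40, 4.66, 3.08, 5.87),
    c_n = c(5.75, 3.03, 3.20, 3.07, 2.88, 2.80, 2.85,
            3.14, 3.07, 3.29, 3.14, 3.05, 2.91),
    c_n_sd = c(0.00, 0.06, 0.03, 0.37, 0.04, 0.01, 0.04,
               0.02, 0.06, 0.10, 0.20, 0.17, 0.08),
    stringsAsFactors = FALSE)
}

#' Reference fitted incorporation-model parameters
#'
#' The published parameter estimates (mean, SE) and fit quality for both
#' incorporation models, each isotope and each diet of the reference trial:
#' equilibrium value `delta_eq`, the model rate parameter (`c` for the
#' growth-based model G, `m` per day for the time-based model D) and R^2.
#' The derived turnover columns printed alongside these parameters can be
#' recomputed with [derive_turnover_metrics()]; two printed cells (model G,
#' d13C, A11: G95 and the discrimination factor) are known not to be
#' reproducible from their own printed parameters (see the package
#' vignette).
#'
#' @return data.frame with columns `isotope`, `model`, `diet_group`,
#'   `delta_eq`, `se_delta_eq`, `rate`, `se_rate`, `r2`.
#' @examples
#' k <- hreidi_kinetics()
#' subset(k, model == "G" & isotope == "d13C")
#' @export
hreidi_kinetics <- function() {
  data.frame(
    isotope = rep(c("d13C", "d15N"), each = 4),
    model = rep(c("G", "G", "D", "D"), 2),
    diet_group = rep(c("A6", "A11"), 4),
    delta_eq = c(-16.3, -15.7, -16.2, -15.6, 14.1, 14.9, 14.2, 14.6),
    se_delta_eq = c(0.5, 0.4, 0.9, 0.8, 0.3, 0.5, 0.5, 0.1),
    rate = c(-1.474, -1.037, 0.040, 0.035, -1.326, -0.844, 0.041, 0.030),
    se_rate = c(0.489, 0.103, 0.070, 0.047, 0.269, 0.176, 0.018, 0.008),
    r2 = c(0.831, 0.776, 0.816, 0.828, 0.934, 0.959, 0.916, 0.944),
    stringsAsFactors = FALSE)
}

#' Reference prey isotope baselines
#'
#' Mean and standard deviation of the lipid-normalized prey isotope values
#' in the reference trial. `d13C_curve`/`d15N_curve` attributes are not
#' needed: discrimination factors in the reference analysis use the
#' slightly more precise Artemia values -18.03 and 12.27 permil that
#' accompany the fitted curves; those are included as prey
#' `"artemia_curve"`.
#'
#' @return data.frame with columns `prey`, `d13C`, `d13C_sd`, `d15N`,
#'   `d15N_sd`.
#' @export
hreidi_prey <- function() {
  data.frame(
    prey = c("copepod", "artemia", "artemia_curve"),
    d13C = c(-21.1, -18.0, -18.03),
    d13C_sd = c(0.7, 1.9, NA),
    d15N = c(5.2, 12.3, 12.27),
    d15N_sd = c(0.4, 0.8, NA),
    stringsAsFactors = FALSE)
}
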