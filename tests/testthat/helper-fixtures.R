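# Shared fixtures: the standard post-switch sampling grid and a noise-free
# series generator for each model.

days_since_switch_a6 <- c(0, 5, 12, 19, 26, 40, 54)

noise_free_g <- function(delta_eq, a, c, k = 0.0620,
                         t = days_since_switch_a6) {
  wr <- exp(k * t)
  list(wr = wr, delta = predict_model_g(wr, delta_eq, a, c))
}

noise_free_d <- function(delta_eq, a, m, k = 0.0620,
                         t = days_since_switch_a6) {
  list(t = t, delta = predict_model_d(t, delta_eq, a, m, k))
}

# Observation table for a single replicate growing exactly exponentially.
exp_series <- function(w0 = 0.80, k = 0.0620, days = c(6, 11, 18, 25, 32, 46, 60),
                       switch_day = 6) {
  data.frame(day = days,
             dry_weight_mg = w0 * exp(k * (days - switch_day)))
}
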