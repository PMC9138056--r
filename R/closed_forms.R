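# Closed-form incorporation models and derived turnover algebra.
# All functions are pure and vectorized where sensible.

#' Growth-based incorporation model
#'
#' Evaluates \eqn{\delta = \delta_{eq} + a W_R^c}: tissue isotope value as a
#' power function of the fold increase in body mass since the diet switch.
#' With \eqn{c = -1} this is the simple dilution model (old tissue diluted by
#' new biomass only); \eqn{c < -1} indicates additional metabolic turnover.
#'
#' @param wr fold increase in dry weight since the switch (\eqn{W_t/W_i});
#'   must be positive, normally \eqn{\ge 1}.
#' @param delta_eq equilibrium isotope value (permil).
#' @param a offset \eqn{\delta_i - \delta_{eq}} (permil).
#' @param c metabolic decay constant (dimensionless, negative for a system
#'   approaching equilibrium).
#' @return predicted isotope value(s), permil.
#' @examples
#' predict_model_g(2, delta_eq = 0, a = 1, c = -1)  # 0.5
#' @seealso [predict_model_d()], [fit_model_g()]
#' @export
predict_model_g <- function(wr, delta_eq, a, c) {
  stopifnot(is.numeric(wr), is.finite(delta_eq), is.finite(a), is.finite(c))
  if (any(!is.finite(wr)) || any(wr <= 0))
    stop("'wr' must be positive and finite (fractional power of a non-positive base)")
  delta_eq + a * wr^c
}

#' Time-based incorporation model
#'
#' Evaluates \eqn{\delta = \delta_{eq} + a e^{-(m+k)t}}: exponential
#' relaxation toward diet equilibrium at combined rate metabolism plus
#' growth. At \eqn{t = 0} the value is \eqn{\delta_{eq} + a = \delta_i}.
#'
#' @param t days since the diet switch, \eqn{\ge 0}.
#' @param delta_eq equilibrium isotope value (permil).
#' @param a offset \eqn{\delta_i - \delta_{eq}} (permil).
#' @param m metabolic constant (per day).
#' @param k specific growth rate (per day).
#' @return predicted isotope value(s), permil.
#' @examples
#' predict_model_d(1, delta_eq = 0, a = 8, m = log(2), k = 0)  # 4
#' @export
predict_model_d <- function(t, delta_eq, a, m, k) {
  stopifnot(is.numeric(t), is.finite(delta_eq), is.finite(a),
            is.finite(m), is.finite(k))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be >= 0: the model is undefined before the diet switch")
  delta_eq + a * exp(-(m + k) * t)
}

#' Specific growth rate from endpoint dry weights
#'
#' \eqn{k = \ln(W_t/W_i)/t}, the per-day exponential growth rate implied by
#' two dry-weight measurements.
#'
#' @param w_i dry weight at the diet switch (mg), positive.
#' @param w_t dry weight at sampling (mg), positive.
#' @param t days elapsed, positive.
#' @return growth rate, per day.
#' @examples
#' growth_rate_k(0.80, 22.78, 54)  # ~0.062 / day
#' @export
growth_rate_k <- function(w_i, w_t, t) {
  if (any(!is.finite(w_i)) || any(w_i <= 0) || any(!is.finite(w_t)) || any(w_t <= 0))
    stop("dry weights must be positive and finite")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive")
  log(w_t / w_i) / t
}

#' Turnover expressed as fold increase in body mass (model G)
#'
#' Solves the growth-based model for the mass increase at which a given
#' percentage \eqn{\alpha} of the isotopic shift is complete:
#' \eqn{G_\alpha = e^{\ln(1 - \alpha/100)/c}}. \eqn{G_{50}} is the half-life
#' in fold-mass units; \eqn{G_{95}} is taken as practical equilibrium.
#'
#' @param c metabolic decay constant, strictly negative.
#' @param alpha percentage turnover in (0, 100); may be a vector.
#' @return fold increase(s) in dry weight, \eqn{\ge 1}.
#' @examples
#' turnover_weight_fold(-1, 50)      # 2: dilution model doubles biomass
#' turnover_weight_fold(-1.474, 50)  # ~1.6
#' @export
turnover_weight_fold <- function(c, alpha) {
  if (!is.finite(c) || c >= 0)
    stop("'c' must be negative: c >= 0 never approaches equilibrium")
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 100))
    stop("'alpha' must lie strictly between 0 and 100")
  exp(log(1 - alpha / 100) / c)
}

#' Turnover expressed in days (model D)
#'
#' Chronological time to a given percentage \eqn{\alpha} of the isotopic
#' shift under the time-based model:
#' \eqn{D_\alpha = |\ln(1 - \alpha/100)|/(m + k)}. The absolute value makes
#' the result a positive duration (the raw logarithm is negative).
#'
#' @param m metabolic constant (per day).
#' @param k specific growth rate (per day); `m + k` must be positive.
#' @param alpha percentage turnover in (0, 100); may be a vector.
#' @return days to \eqn{\alpha}\% turnover.
#' @examples
#' turnover_days(0, log(2), 50)  # 1 day
#' @export
turnover_days <- function(m, k, alpha) {
  if (!is.finite(m) || !is.finite(k) || (m + k) <= 0)
    stop("'m + k' must be positive: the tissue never approaches equilibrium")
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 100))
    stop("'alpha' must lie strictly between 0 and 100")
  abs(log(1 - alpha / 100)) / (m + k)
}

#' Partition turnover between growth and metabolism
#'
#' From the half-life fold-mass \eqn{G_{50}}, the contribution of growth
#' dilution is \eqn{P_g = 2(G_{50} - 1)/G_{50}} and of metabolic replacement
#' \eqn{P_m = (2 - G_{50})/G_{50}}. The raw \eqn{P_m} is negative whenever
#' \eqn{G_{50} > 2}; it is clipped to \[0, 1\] and \eqn{P_g} set to
#' \eqn{1 - P_m}, so the fractions always sum to one (a \eqn{G_{50} \ge 2}
#' reads as "no metabolic contribution").
#'
#' @param g50 half-life fold increase in mass, \eqn{\ge 1}.
#' @return named numeric vector `c(p_g, p_m)`, fractions summing to 1.
#' @examples
#' partition_turnover(1.6)  # p_m = 0.25
#' partition_turnover(2.5)  # p_m clipped to 0
#' @export
partition_turnover <- function(g50) {
  if (!is.finite(g50) || g50 < 1)
    stop("'g50' must be >= 1 (a half-life cannot precede the switch)")
  p_m <- (2 - g50) / g50
  p_m <- min(max(p_m, 0), 1)
  c(p_g = 1 - p_m, p_m = p_m)
}

#' Diet-tissue discrimination factor
#'
#' \eqn{\Delta\delta = \delta_{eq} - \delta_{diet}}: the offset between
#' fully equilibrated consumer tissue and its diet. Both values must refer
#' to the same isotope; supplying mismatched isotope labels is an error.
#'
#' @param delta_eq equilibrium tissue isotope value (permil).
#' @param delta_diet diet (prey baseline) isotope value (permil).
#' @param isotope optional isotope label for the tissue value
#'   (`"d13C"` or `"d15N"`).
#' @param diet_isotope optional isotope label for the diet value; defaults
#'   to `isotope`.
#' @return discrimination factor, permil.
#' @examples
#' discrimination_factor(-16.3, -18.03)  # ~1.7 permil
#' @export
discrimination_factor <- function(delta_eq, delta_diet,
                                  isotope = NULL, diet_isotope = isotope) {
  stopifnot(is.finite(delta_eq), is.finite(delta_diet))
  if (!is.null(isotope) && !is.null(diet_isotope) &&
      !identical(isotope, diet_isotope))
    stop(sprintf("isotope mismatch: tissue is %s but diet baseline is %s",
                 isotope, diet_isotope))
  delta_eq - delta_diet
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}.
#'
#' @param observed observed values.
#' @param predicted model predictions, same length.
#' @return R-squared (can be negative for a model worse than the mean).
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero variance in 'observed': R-squared is undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Loose plausibility screen for delta values; flags, never rejects.
# Ranges: d13C in [-60, 10], d15N in [-20, 40] permil.
flag_implausible_delta <- function(delta, isotope) {
  rng <- switch(isotope,
                d13C = c(-60, 10),
                d15N = c(-20, 40),
                stop("unknown isotope: ", isotope))
  !is.na(delta) & (delta < rng[1] | delta > rng[2])
}
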