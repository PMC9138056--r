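# Nonlinear least-squares estimation of the incorporation models.
#
# Both fitters return an object of class "incorp_fit". Optimization uses
# bounded trust-region least squares (stats::nls, algorithm "port") with a
# Levenberg-Marquardt fallback (minpack.lm::nlsLM). Starting values exploit
# the monotone trajectories: delta_eq from the last observation, a from the
# endpoint difference, c = -1 (pure dilution), m = 0.

# Bounds. c < 0 is required for equilibrium approach; c in [-10, -0.01].
# m < 0 is biologically unidentified in this design; m in [0, 1].
.bounds_g <- list(lower = c(delta_eq = -Inf, a = -Inf, c = -10),
                  upper = c(delta_eq = Inf, a = Inf, c = -0.01))
.bounds_d <- list(lower = c(delta_eq = -Inf, a = -Inf, m = 0),
                  upper = c(delta_eq = Inf, a = Inf, m = 1))

#' Fit the growth-based incorporation model
#'
#' Estimates \eqn{(\delta_{eq}, a, c)} in
#' \eqn{\delta = \delta_{eq} + a W_R^c} by bounded nonlinear least squares.
#' \eqn{c} is constrained to \eqn{[-10, -0.01]} (equilibrium approach).
#' Non-convergence and degenerate inputs are reported through the
#' `converged` flag and `flags` field, never as an exception.
#'
#' @param wr fold mass increases \eqn{W_R \ge 1}; at least 4 distinct values.
#' @param delta observed isotope values (permil), same length.
#' @param start optional named list/vector of starting values
#'   (`delta_eq`, `a`, `c`).
#' @param isotope,diet optional labels carried into the result.
#' @return an object of class `incorp_fit`; see [incorp_fit methods]
#'   [print.incorp_fit()], [summary.incorp_fit()], [predict.incorp_fit()],
#'   [turnover()], [discrimination()].
#' @examples
#' wr <- exp(0.062 * c(0, 5, 12, 19, 26, 40, 54))
#' delta <- predict_model_g(wr, -16.3, -4.4, -1.474)
#' fit <- fit_model_g(wr, delta)
#' coef(fit)
#' @export
fit_model_g <- function(wr, delta, start = NULL, isotope = NULL, diet = NULL) {
  stopifnot(length(wr) == length(delta))
  if (any(!is.finite(wr)) || any(wr < 1))
    stop("all 'wr' must be finite and >= 1 (weights at or after the switch)")
  if (length(unique(wr)) < 4)
    stop("need at least 4 distinct 'wr' values to fit 3 parameters")
  o <- order(wr)
  dat <- data.frame(x = wr[o], delta = delta[o])
  if (is.null(start))
    start <- list(delta_eq = dat$delta[nrow(dat)],
                  a = dat$delta[1] - dat$delta[nrow(dat)],
                  c = -1)
  new_incorp_fit(
    model = "G",
    formula = delta ~ delta_eq + a * x^c,
    data = dat, start = start, bounds = .bounds_g,
    k = NULL, isotope = isotope, diet = diet)
}

#' Fit the time-based incorporation model
#'
#' Estimates \eqn{(\delta_{eq}, a, m)} in
#' \eqn{\delta = \delta_{eq} + a e^{-(m+k)t}} with the growth rate `k`
#' supplied externally and held fixed (it is measured from dry weights, not
#' estimated from isotope data). \eqn{m} is constrained to \eqn{[0, 1]}.
#'
#' @param t days since the diet switch, \eqn{\ge 0}; at least 4 distinct
#'   values.
#' @param delta observed isotope values (permil), same length.
#' @param k fixed specific growth rate (per day), see
#'   [replicate_growth_rate()].
#' @param start optional named starting values (`delta_eq`, `a`, `m`).
#' @param isotope,diet optional labels carried into the result.
#' @return an object of class `incorp_fit`.
#' @examples
#' t <- c(0, 5, 12, 19, 26, 40, 54)
#' delta <- predict_model_d(t, 14.6, -6.9, 0.030, 0.0694)
#' fit <- fit_model_d(t, delta, k = 0.0694)
#' coef(fit)
#' @export
fit_model_d <- function(t, delta, k, start = NULL, isotope = NULL,
                        diet = NULL) {
  stopifnot(length(t) == length(delta), is.finite(k))
  if (any(!is.finite(t)) || any(t < 0)) stop("all 't' must be >= 0")
  if (length(unique(t)) < 4)
    stop("need at least 4 distinct 't' values to fit 3 parameters")
  o <- order(t)
  dat <- data.frame(x = t[o], delta = delta[o])
  if (is.null(start))
    start <- list(delta_eq = dat$delta[nrow(dat)],
                  a = dat$delta[1] - dat$delta[nrow(dat)],
                  m = 0)
  new_incorp_fit(
    model = "D",
    formula = delta ~ delta_eq + a * exp(-(m + k) * x),
    data = dat, start = start, bounds = .bounds_d,
    k = k, isotope = isotope, diet = diet)
}

# Shared fitting engine.
new_incorp_fit <- function(model, formula, data, start, bounds, k,
                           isotope, diet) {
  pnames <- names(bounds$lower)
  flags <- character()

  # Degenerate input: no isotopic signal at all.
  if (stats::sd(data$delta) == 0) {
    cf <- c(mean(data$delta), 0, NA_real_)
    names(cf) <- pnames
    return(structure(list(
      model = model, coefficients = cf,
      se = stats::setNames(rep(NA_real_, 3), pnames),
      vcov = matrix(NA_real_, 3, 3, dimnames = list(pnames, pnames)),
      k = k, r2 = NA_real_, sigma = 0, n_obs = nrow(data),
      fitted = rep(mean(data$delta), nrow(data)),
      residuals = rep(0, nrow(data)), data = data,
      converged = FALSE,
      flags = "degenerate: constant delta, rate parameter unidentifiable",
      isotope = isotope, diet = diet), class = "incorp_fit"))
  }

  fit <- tryCatch(
    withCallingHandlers(
      stats::nls(formula, data = data, start = start,
                 algorithm = "port",
                 lower = bounds$lower, upper = bounds$upper,
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)),
      warning = function(w) {
        # optimizer diagnostics go into flags, not the console
        flags <<- c(flags, paste0("optimizer: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    flags <- c(flags, paste0("port optimizer failed (", conditionMessage(fit),
                             "); Levenberg-Marquardt fallback used"))
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = start,
                        lower = bounds$lower, upper = bounds$upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    cf <- stats::setNames(rep(NA_real_, 3), pnames)
    return(structure(list(
      model = model, coefficients = cf, se = cf,
      vcov = matrix(NA_real_, 3, 3, dimnames = list(pnames, pnames)),
      k = k, r2 = NA_real_, sigma = NA_real_, n_obs = nrow(data),
      fitted = rep(NA_real_, nrow(data)),
      residuals = rep(NA_real_, nrow(data)), data = data,
      converged = FALSE,
      flags = c(flags, paste0("fit failed: ", conditionMessage(fit))),
      isotope = isotope, diet = diet), class = "incorp_fit"))
  }

  converged <- if (!is.null(fit$convInfo)) isTRUE(fit$convInfo$isConv) else TRUE
  if (!converged) flags <- c(flags, "optimizer did not report convergence")
  cf <- stats::coef(fit)[pnames]
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- if (!is.null(sm)) sm$coefficients[pnames, "Std. Error"] else
    stats::setNames(rep(NA_real_, 3), pnames)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(pnames, pnames)))
  fitted_vals <- as.numeric(stats::fitted(fit))
  res <- data$delta - fitted_vals
  r2 <- goodness_of_fit(data$delta, fitted_vals)

  structure(list(
    model = model, coefficients = cf, se = se, vcov = vc, k = k,
    r2 = r2, sigma = sqrt(sum(res^2) / max(1, nrow(data) - 3)),
    n_obs = nrow(data), fitted = fitted_vals, residuals = res,
    data = data, converged = converged, flags = flags,
    isotope = isotope, diet = diet), class = "incorp_fit")
}

rate_name <- function(object) if (object$model == "G") "c" else "m"

x_label <- function(object)
  if (object$model == "G") "fold mass increase (WR)" else "days since switch"

#' @export
print.incorp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Isotope incorporation model %s (%s)\n", x$model,
              if (x$model == "G") "growth-based: delta_eq + a * WR^c"
              else "time-based: delta_eq + a * exp(-(m + k) t)"))
  if (!is.null(x$isotope) || !is.null(x$diet))
    cat("  ", paste(c(x$isotope, x$diet), collapse = ", "), "\n", sep = "")
  print(round(x$coefficients, digits))
  if (x$model == "D") cat(sprintf("k (fixed): %.4f / day\n", x$k))
  cat(sprintf("R2 = %.3f on %d observations; converged: %s\n",
              x$r2, x$n_obs, x$converged))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Summarize an incorporation model fit
#'
#' @param object an `incorp_fit`.
#' @param alphas turnover percentages for the derived metrics.
#' @param ... unused.
#' @return a list of class `summary.incorp_fit` with the coefficient table,
#'   fit quality and derived turnover metrics.
#' @export
summary.incorp_fit <- function(object, alphas = c(50, 95), ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  out <- list(model = object$model, coefficients = tab, r2 = object$r2,
              sigma = object$sigma, n_obs = object$n_obs, k = object$k,
              converged = object$converged, flags = object$flags,
              turnover = tryCatch(turnover(object, alphas),
                                  error = function(e) NULL))
  class(out) <- "summary.incorp_fit"
  out
}

#' @export
print.summary.incorp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Incorporation model %s: n = %d, R2 = %.3f, sigma = %.3f\n",
              x$model, x$n_obs, x$r2, x$sigma))
  stats::printCoefmat(x$coefficients, digits = digits)
  if (x$model == "D") cat(sprintf("k (fixed): %.4f / day\n", x$k))
  if (!is.null(x$turnover)) {
    cat("Turnover:\n")
    print(round(x$turnover, 2))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.incorp_fit <- function(object, ...) object$coefficients

#' @export
vcov.incorp_fit <- function(object, ...) object$vcov

#' @export
residuals.incorp_fit <- function(object, ...) object$residuals

#' @export
fitted.incorp_fit <- function(object, ...) object$fitted

#' @export
predict.incorp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.numeric(newdata)) newdata
       else newdata$x
  cf <- object$coefficients
  if (object$model == "G")
    predict_model_g(x, cf[["delta_eq"]], cf[["a"]], cf[["c"]])
  else
    predict_model_d(x, cf[["delta_eq"]], cf[["a"]], cf[["m"]], object$k)
}

#' Wald confidence intervals for incorporation model parameters
#'
#' Normal-theory intervals `estimate +/- t(df) * SE` with
#' `df = n_obs - 3`.
#'
#' @param object an `incorp_fit`.
#' @param parm parameters to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix of lower/upper bounds.
#' @export
confint.incorp_fit <- function(object, parm = names(object$coefficients),
                               level = 0.95, ...) {
  df <- max(1, object$n_obs - length(object$coefficients))
  q <- stats::qt(1 - (1 - level) / 2, df)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - q * se, est + q * se)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' Simulate responses from a fitted incorporation model
#'
#' Draws new isotope series at the fitted parameters plus Gaussian residual
#' noise at the fit's residual standard deviation.
#'
#' @param object an `incorp_fit`.
#' @param nsim number of simulated series.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.incorp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$sigma), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "x") <- object$data$x
  out
}

#' @export
plot.incorp_fit <- function(x, n_curve = 200, ...) {
  dat <- x$data
  graphics::plot(dat$x, dat$delta, xlab = x_label(x),
                 ylab = "delta (per mil)",
                 main = sprintf("Incorporation model %s", x$model), ...)
  xs <- seq(min(dat$x), max(dat$x), length.out = n_curve)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = x$coefficients[["delta_eq"]], lty = 2)
  invisible(x)
}

#' Turnover metrics of a fitted incorporation model
#'
#' For a model-G fit, \eqn{G_\alpha} fold-mass turnover from the fitted `c`;
#' for a model-D fit, \eqn{D_\alpha} in days from the fitted `m` and fixed
#' `k`. See [turnover_weight_fold()] and [turnover_days()].
#'
#' @param object an `incorp_fit`, or a fitted rate for the default method.
#' @param alphas percentages of turnover (default 50 and 95).
#' @param ... passed on.
#' @return named numeric vector, e.g. `c(g50 = ..., g95 = ...)`.
#' @export
turnover <- function(object, ...) UseMethod("turnover")

#' @rdname turnover
#' @export
turnover.incorp_fit <- function(object, alphas = c(50, 95), ...) {
  cf <- object$coefficients
  if (object$model == "G") {
    out <- turnover_weight_fold(cf[["c"]], alphas)
    names(out) <- paste0("g", alphas)
  } else {
    out <- turnover_days(cf[["m"]], object$k, alphas)
    names(out) <- paste0("d", alphas)
  }
  out
}

#' Growth/metabolism partition of a fitted model
#'
#' For a model-G fit the half-life fold mass is the fitted \eqn{G_{50}}; for
#' a model-D fit \eqn{D_{50}} is first converted to fold mass through the
#' exponential growth curve (\eqn{G_{50} = e^{k D_{50}}}). The partition is
#' then [partition_turnover()].
#'
#' @param object an `incorp_fit`.
#' @param ... unused.
#' @return named numeric vector `c(p_g, p_m)`.
#' @export
partition <- function(object, ...) UseMethod("partition")

#' @rdname partition
#' @export
partition.incorp_fit <- function(object, ...) {
  g50 <- if (object$model == "G")
    turnover_weight_fold(object$coefficients[["c"]], 50)
  else
    exp(object$k * turnover_days(object$coefficients[["m"]], object$k, 50))
  partition_turnover(max(1, g50))
}

#' Diet-tissue discrimination from a fitted model
#'
#' \eqn{\Delta\delta} between the fitted equilibrium value and a prey
#' baseline; see [discrimination_factor()].
#'
#' @param object an `incorp_fit`.
#' @param delta_diet prey baseline isotope value (permil).
#' @param ... passed to [discrimination_factor()].
#' @return discrimination factor, permil.
#' @export
discrimination <- function(object, delta_diet, ...) UseMethod("discrimination")

#' @rdname discrimination
#' @export
discrimination.incorp_fit <- function(object, delta_diet, ...) {
  discrimination_factor(object$coefficients[["delta_eq"]], delta_diet,
                        isotope = object$isotope, ...)
}
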