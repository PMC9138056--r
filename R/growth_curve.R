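# Weight-vs-time curves used to move turnover estimates between the
# fold-mass scale (model G) and the chronological scale (model D).

#' Build a growth curve linking days and fold mass increase
#'
#' Constructs an invertible relationship between days since the diet switch
#' and the fold increase in dry weight \eqn{W_R}. Two forms are available:
#'
#' \describe{
#'   \item{`"loglinear"`}{monotone piecewise-linear interpolation of
#'     \eqn{\ln W} against day through observed (day, weight) pairs;
#'     round-trips exactly within the observed range.}
#'   \item{`"exponential"`}{the closed form \eqn{W_R = e^{k d}} implied by a
#'     constant specific growth rate `k`; needs no observed weights.}
#' }
#'
#' @param day sampling days (absolute, e.g. days after release); required
#'   for `"loglinear"`.
#' @param weight dry weights (mg) at `day`, positive; required for
#'   `"loglinear"`.
#' @param switch_day day of the diet switch; must be one of `day` for
#'   `"loglinear"`.
#' @param method `"loglinear"` or `"exponential"`.
#' @param k specific growth rate (per day), required for `"exponential"`.
#' @return an object of class `growth_curve`.
#' @examples
#' gc <- growth_curve(method = "exponential", k = 0.062, switch_day = 6)
#' convert_turnover_scale(gc, 1.6, "weight_to_days")  # ~7.6 days
#' @export
growth_curve <- function(day = NULL, weight = NULL, switch_day = NULL,
                         method = c("loglinear", "exponential"), k = NULL) {
  method <- match.arg(method)
  if (method == "exponential") {
    if (is.null(k) || !is.finite(k) || k <= 0)
      stop("'k' must be a positive growth rate for the exponential curve")
    obj <- list(method = method, k = k, switch_day = switch_day)
  } else {
    if (is.null(day) || is.null(weight) || length(day) == 0)
      stop("empty curve: 'day' and 'weight' observations are required")
    stopifnot(length(day) == length(weight))
    if (any(weight <= 0)) stop("weights must be positive")
    o <- order(day)
    day <- day[o]; weight <- weight[o]
    if (anyDuplicated(day)) stop("duplicate days in growth curve")
    if (is.null(switch_day)) switch_day <- day[1]
    if (!switch_day %in% day)
      stop("'switch_day' must be one of the observed days")
    lw <- log(weight)
    if (any(diff(lw) <= 0))
      stop("weights must be strictly increasing for an invertible curve")
    obj <- list(method = method, day = day, log_weight = lw,
                switch_day = switch_day,
                log_w_switch = lw[match(switch_day, day)])
  }
  class(obj) <- "growth_curve"
  obj
}

#' @export
print.growth_curve <- function(x, ...) {
  if (x$method == "exponential") {
    cat(sprintf("Exponential growth curve: k = %.4f / day\n", x$k))
  } else {
    cat(sprintf(
      "Log-linear growth curve: %d points, days %g-%g, switch at day %g\n",
      length(x$day), min(x$day), max(x$day), x$switch_day))
  }
  invisible(x)
}

#' Convert a turnover estimate between fold-mass and day scales
#'
#' Moves \eqn{G_\alpha} (fold mass increase) to \eqn{D_\alpha} (days since
#' switch) or back through a [growth_curve()]. On the log-linear curve the
#' two directions are exact inverses within the observed range; querying
#' outside that range triggers a warning (linear extrapolation of
#' \eqn{\ln W}).
#'
#' @param curve a [growth_curve()].
#' @param value the estimate to convert: fold mass (\eqn{\ge 1}) for
#'   `"weight_to_days"`, days (\eqn{\ge 0}) for `"days_to_weight"`.
#' @param direction `"weight_to_days"` or `"days_to_weight"`.
#' @return the converted estimate (days, or fold mass).
#' @export
convert_turnover_scale <- function(curve, value,
                                   direction = c("weight_to_days",
                                                 "days_to_weight")) {
  if (!inherits(curve, "growth_curve")) stop("'curve' must be a growth_curve")
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), all(is.finite(value)))
  if (direction == "weight_to_days" && any(value < 1))
    stop("fold-mass values must be >= 1")
  if (direction == "days_to_weight" && any(value < 0))
    stop("day values must be >= 0")

  if (curve$method == "exponential") {
    return(switch(direction,
                  weight_to_days = log(value) / curve$k,
                  days_to_weight = exp(curve$k * value)))
  }

  d_rel <- curve$day - curve$switch_day   # days since switch at each knot
  lwr <- curve$log_weight - curve$log_w_switch  # log W_R at each knot
  if (direction == "days_to_weight") {
    if (any(value > max(d_rel)) || any(value < min(d_rel)))
      warning("converting outside the observed day range; extrapolating")
    lw <- stats::approx(d_rel, lwr, xout = value, rule = 2)$y
    out <- exp(ifelse(value > max(d_rel) | value < min(d_rel),
                      extrapolate(d_rel, lwr, value), lw))
  } else {
    lv <- log(value)
    if (any(lv > max(lwr)) || any(lv < min(lwr)))
      warning("converting outside the observed weight range; extrapolating")
    d <- stats::approx(lwr, d_rel, xout = lv, rule = 2)$y
    out <- ifelse(lv > max(lwr) | lv < min(lwr),
                  extrapolate(lwr, d_rel, lv), d)
  }
  out
}

# Linear extrapolation beyond the first/last knot.
extrapolate <- function(x, y, xout) {
  n <- length(x)
  lo <- (y[2] - y[1]) / (x[2] - x[1])
  hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  ifelse(xout < x[1], y[1] + lo * (xout - x[1]),
         ifelse(xout > x[n], y[n] + hi * (xout - x[n]),
                stats::approx(x, y, xout = xout)$y))
}
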