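# Preprocessing: raw observation tables -> model-ready series.

#' Default lipid-normalization factors
#'
#' Taxon- and isotope-specific multiplicative conversion factors applied to
#' raw delta values of lipid-rich samples (C:N > 3.56). The defaults are the
#' internal conversion factors for the copepod prey, Artemia nauplii prey
#' and seahorse juvenile tissue used throughout this package. The convention
#' is multiplicative (corrected = factor x raw); to use an additive offset
#' convention, transform values before fitting instead — the factors are
#' deliberately exposed as data so they can be swapped without code changes.
#'
#' @return data.frame with columns `taxon`, `f_d13C`, `f_d15N`.
#' @export
lipid_factors <- function() {
  data.frame(
    taxon  = c("copepod", "artemia", "seahorse"),
    f_d13C = c(0.940, 0.922, 0.903),
    f_d15N = c(1.370, 1.059, 1.019),
    stringsAsFactors = FALSE
  )
}

#' Does a sample need lipid normalization?
#'
#' Lipids are depleted in 13C; samples with high lipid content (C:N mass
#' ratio above 3.56) are normalized before model fitting.
#'
#' @param c_n C:N mass ratio(s), positive.
#' @return logical: `TRUE` where `c_n > 3.56` (strict).
#' @export
needs_lipid_correction <- function(c_n) {
  if (any(!is.finite(c_n)) || any(c_n <= 0)) stop("'c_n' must be positive")
  c_n > 3.56
}

#' Lipid-normalize a raw isotope value
#'
#' Applies the multiplicative taxon/isotope conversion factor:
#' corrected = factor x raw.
#'
#' @param delta_raw raw delta value(s), permil.
#' @param taxon one of the taxa in `factors`.
#' @param isotope `"d13C"` or `"d15N"`.
#' @param factors factor table, see [lipid_factors()].
#' @return normalized delta value(s), permil.
#' @examples
#' lipid_normalize(-20, "seahorse", "d13C")  # -18.06
#' @export
lipid_normalize <- function(delta_raw, taxon, isotope,
                            factors = lipid_factors()) {
  col <- paste0("f_", isotope)
  if (!col %in% names(factors) || !taxon %in% factors$taxon)
    stop(sprintf("no lipid-normalization factor for taxon '%s', isotope '%s'",
                 taxon, isotope))
  f <- factors[[col]][match(taxon, factors$taxon)]
  if (is.na(f))
    stop(sprintf("no lipid-normalization factor for taxon '%s', isotope '%s'",
                 taxon, isotope))
  delta_raw * f
}

#' Apply lipid normalization to an observation table
#'
#' Normalizes `d13C` and `d15N` of every row whose C:N ratio exceeds 3.56
#' (see [needs_lipid_correction()]); other rows pass through unchanged.
#'
#' @param obs observation data.frame (see [read_observations()]).
#' @param taxon taxon label used to look up factors (default `"seahorse"`).
#' @param factors factor table, see [lipid_factors()].
#' @return the table with normalized isotope columns and a logical
#'   `lipid_normalized` column recording which rows were corrected.
#' @export
normalize_observations <- function(obs, taxon = "seahorse",
                                   factors = lipid_factors()) {
  sel <- needs_lipid_correction(obs$C_N)
  obs$d13C[sel] <- lipid_normalize(obs$d13C[sel], taxon, "d13C", factors)
  obs$d15N[sel] <- lipid_normalize(obs$d15N[sel], taxon, "d15N", factors)
  obs$lipid_normalized <- sel
  obs
}

obs_columns <- c("diet_group", "replicate", "day", "dry_weight_mg",
                 "d13C", "d15N", "C_N")

#' Read a diet-switch observation table
#'
#' Reads a delimited text file of per-sampling-day observations with header
#' columns `diet_group, replicate, day, dry_weight_mg, d13C, d15N, C_N`
#' (empty fields become `NA`). Values outside loose plausibility ranges
#' (\eqn{-60 \le \delta^{13}C \le 10}; \eqn{-20 \le \delta^{15}N \le 40})
#' are flagged with a warning, never rejected.
#'
#' @param path file path (CSV).
#' @return data.frame of observations.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(obs_columns, names(obs))
  if (length(missing_cols))
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  validate_observations(obs)
  obs
}

validate_observations <- function(obs) {
  if (any(obs$day < 0, na.rm = TRUE)) stop("'day' must be >= 0")
  if (any(obs$dry_weight_mg <= 0, na.rm = TRUE))
    stop("'dry_weight_mg' must be positive")
  if (any(obs$C_N <= 0, na.rm = TRUE)) stop("'C_N' must be positive")
  n13 <- sum(flag_implausible_delta(obs$d13C, "d13C"))
  n15 <- sum(flag_implausible_delta(obs$d15N, "d15N"))
  if (n13 + n15 > 0)
    warning(sprintf(
      "%d d13C and %d d15N values outside plausible ranges (kept, flagged)",
      n13, n15))
  invisible(obs)
}

#' Write an observation table
#'
#' Writes the CSV schema read back by [read_observations()].
#'
#' @param obs observation data.frame.
#' @param path output file path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[, intersect(c(obs_columns, "lipid_normalized"),
                                   names(obs))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prey baseline table
#'
#' Columns: `prey, d13C, d15N` (one row per prey sample or per prey mean).
#'
#' @param path file path (CSV).
#' @return data.frame.
#' @export
read_prey <- function(path) {
  prey <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("prey", "d13C", "d15N")
  if (!all(need %in% names(prey)))
    stop("prey table lacks columns: ",
         paste(setdiff(need, names(prey)), collapse = ", "))
  prey
}

#' Weight ratios relative to the diet switch
#'
#' For one replicate's series, computes \eqn{W_R = W_t / W_i} for every
#' observation at or after the switch day, where \eqn{W_i} is the weight at
#' the switch day itself. No imputation: the switch-day observation must be
#' present.
#'
#' @param series data.frame with columns `day` and `dry_weight_mg` for one
#'   replicate.
#' @param switch_day day of the diet switch.
#' @return data.frame with columns `day`, `w_i`, `w_t`, `w_r`.
#' @export
weight_ratios <- function(series, switch_day) {
  i <- match(switch_day, series$day)
  if (is.na(i))
    stop(sprintf("no observation at switch day %s; cannot form weight ratios",
                 switch_day))
  w_i <- series$dry_weight_mg[i]
  keep <- series$day >= switch_day
  data.frame(day = series$day[keep],
             w_i = w_i,
             w_t = series$dry_weight_mg[keep],
             w_r = series$dry_weight_mg[keep] / w_i)
}

#' Growth rate of one replicate from endpoint weights
#'
#' Default (`method = "endpoints"`) uses only the switch-day and final-day
#' weights, \eqn{k = \ln(W_{final}/W_{switch}) / (final - switch)}.
#' `method = "regression"` instead regresses \eqn{\ln W} on day over the
#' whole post-switch series (offered for robustness, never the default).
#'
#' @param series data.frame with columns `day` and `dry_weight_mg`.
#' @param switch_day day of the diet switch.
#' @param final_day final experimental day.
#' @param method `"endpoints"` (default) or `"regression"`.
#' @return growth rate, per day.
#' @export
replicate_growth_rate <- function(series, switch_day, final_day,
                                  method = c("endpoints", "regression")) {
  method <- match.arg(method)
  if (method == "regression") {
    keep <- series$day >= switch_day & series$day <= final_day
    if (sum(keep) < 2) stop("need at least 2 observations for regression k")
    fit <- stats::lm(log(dry_weight_mg) ~ day, data = series[keep, ])
    return(unname(stats::coef(fit)[2]))
  }
  i <- match(switch_day, series$day)
  j <- match(final_day, series$day)
  if (is.na(i) || is.na(j))
    stop(sprintf("missing endpoint observation (days %s and %s required)",
                 switch_day, final_day))
  growth_rate_k(series$dry_weight_mg[i], series$dry_weight_mg[j],
                final_day - switch_day)
}

#' Replicate means per diet group and sampling day
#'
#' Averages dry weight and isotope values across replicate tanks, giving the
#' per-day group means that the incorporation models are fitted on.
#'
#' @param obs observation data.frame.
#' @return data.frame with one row per (diet_group, day).
#' @export
replicate_means <- function(obs) {
  agg <- stats::aggregate(
    obs[, c("dry_weight_mg", "d13C", "d15N", "C_N")],
    by = list(diet_group = obs$diet_group, day = obs$day),
    FUN = mean, na.rm = TRUE)
  agg[order(agg$diet_group, agg$day), , drop = FALSE]
}
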