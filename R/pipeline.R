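# End-to-end analysis: observations + prey -> fitted models per diet and
# isotope -> turnover, partition and discrimination report.

#' Derived turnover metrics from kinetic parameters
#'
#' Computes every derived column of the per-model report from a parameter
#' set alone (no fitting): turnover on the model's native scale, its
#' conversion to the other scale through an exponential growth curve with
#' rate `k`, the growth/metabolism partition, and the discrimination
#' factor against a diet baseline.
#'
#' @param model `"G"` (rate is `c`) or `"D"` (rate is `m`).
#' @param delta_eq equilibrium isotope value (permil).
#' @param rate the model rate parameter: `c` (model G, negative) or `m`
#'   (model D, per day).
#' @param k specific growth rate (per day), used by model D and for scale
#'   conversion.
#' @param delta_diet optional diet baseline (permil) for the discrimination
#'   factor.
#' @param alphas turnover percentages (default 50 and 95).
#' @return one-row data.frame with columns `g50`, `g95`, `d50`, `d95`,
#'   `p_g`, `p_m` and (if `delta_diet` given) `delta_delta`.
#' @examples
#' derive_turnover_metrics("G", -16.3, -1.474, k = 0.0620,
#'                         delta_diet = -18.03)
#' @export
derive_turnover_metrics <- function(model, delta_eq, rate, k,
                                    delta_diet = NULL,
                                    alphas = c(50, 95)) {
  stopifnot(model %in% c("G", "D"), length(alphas) == 2)
  if (model == "G") {
    g <- turnover_weight_fold(rate, alphas)
    d <- log(g) / k                      # exponential curve: D = ln(G)/k
  } else {
    d <- turnover_days(rate, k, alphas)
    g <- exp(k * d)                      # exponential curve: G = e^{kD}
  }
  part <- partition_turnover(max(1, g[1]))
  out <- data.frame(g50 = g[1], g95 = g[2], d50 = d[1], d95 = d[2],
                    p_g = part[["p_g"]], p_m = part[["p_m"]])
  if (!is.null(delta_diet))
    out$delta_delta <- discrimination_factor(delta_eq, delta_diet)
  out
}

#' Run the full diet-switch analysis
#'
#' Preprocesses an observation table (optional lipid normalization,
#' replicate means per day, per-replicate growth rates), fits both
#' incorporation models per diet group and isotope, and assembles the
#' per-(diet, isotope, model) report of parameters, fit quality, turnover,
#' partition and discrimination, plus cross-model discrimination averages.
#'
#' Missing series (a diet group with too few sampling days, or a fit
#' failure) yield rows flagged in the `converged` column rather than an
#' error, so partial designs still produce a partial report.
#'
#' @param observations observation data.frame
#'   (see [read_observations()] for the schema).
#' @param prey prey baseline data.frame (`prey`, `d13C`, `d15N`).
#' @param switch_days named vector mapping diet group to switch day;
#'   `NULL` uses each group's earliest sampled day.
#' @param diet_prey name of the post-switch prey in `prey` whose values are
#'   the diet baseline (default `"artemia"`).
#' @param alphas turnover percentages (default 50 and 95).
#' @param normalize apply lipid normalization to seahorse tissue rows with
#'   C:N > 3.56 (default `TRUE`).
#' @param fit_mode `"means"` (default: fit replicate means per day, the
#'   reference treatment) or `"replicates"` (fit each tank, average
#'   estimates; SE is then the between-replicate spread).
#' @param k_method growth-rate estimator passed to
#'   [replicate_growth_rate()].
#' @return an object of class `iso_report`: a data.frame with one row per
#'   (diet, isotope, model) and attributes `discrimination_averages`,
#'   `growth_rates`, `prey_baseline`.
#' @examples
#' exp <- simulate_experiment(default_config(seed = 1))
#' rep <- run_analysis(exp$observations, exp$prey)
#' print(rep)
#' @export
run_analysis <- function(observations, prey,
                         switch_days = NULL,
                         diet_prey = "artemia",
                         alphas = c(50, 95),
                         normalize = TRUE,
                         fit_mode = c("means", "replicates"),
                         k_method = c("endpoints", "regression")) {
  fit_mode <- match.arg(fit_mode)
  k_method <- match.arg(k_method)
  validate_observations(observations)
  if (is.null(prey) || nrow(prey) == 0 || !diet_prey %in% prey$prey)
    stop(sprintf("prey baseline '%s' missing from the prey table", diet_prey))
  baseline <- prey[match(diet_prey, prey$prey), ]

  if (normalize) observations <- normalize_observations(observations)

  diets <- unique(observations$diet_group)
  if (is.null(switch_days)) {
    switch_days <- vapply(
      diets, function(d) min(observations$day[observations$diet_group == d]),
      numeric(1))
  }

  rows <- list(); fits <- list(); krates <- numeric()
  for (diet in diets) {
    dobs <- observations[observations$diet_group == diet, ]
    sw <- switch_days[[diet]]
    final_day <- max(dobs$day)
    # mean of per-replicate endpoint growth rates
    ks <- vapply(unique(dobs$replicate), function(r)
      replicate_growth_rate(dobs[dobs$replicate == r, ], sw, final_day,
                            method = k_method),
      numeric(1))
    k <- mean(ks)
    krates[[diet]] <- k
    means <- replicate_means(dobs)
    means <- means[means$day >= sw, ]
    wr <- weight_ratios(means, sw)
    # Cross-scale conversions go through the observed weight curve
    # (log-linear interpolation); exponential fallback if the mean series
    # is not strictly increasing.
    curve <- tryCatch(
      growth_curve(means$day, means$dry_weight_mg, switch_day = sw),
      error = function(e) growth_curve(method = "exponential", k = k,
                                       switch_day = sw))

    for (iso in c("d13C", "d15N")) {
      for (model in c("G", "D")) {
        fit <- tryCatch({
          if (fit_mode == "means") {
            if (model == "G")
              fit_model_g(wr$w_r, means[[iso]], isotope = iso, diet = diet)
            else
              fit_model_d(means$day - sw, means[[iso]], k = k,
                          isotope = iso, diet = diet)
          } else {
            fit_replicates(dobs, iso, diet, model, sw, ks)
          }
        }, error = function(e) e)
        rows[[length(rows) + 1]] <-
          report_row(diet, iso, model, fit, k, baseline[[iso]], alphas,
                     curve)
        fits[[paste(diet, iso, model, sep = ".")]] <- fit
      }
    }
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "discrimination_averages") <- discrimination_table(report)
  attr(report, "growth_rates") <- krates
  attr(report, "prey_baseline") <- baseline
  attr(report, "alphas") <- alphas
  attr(report, "fits") <- fits
  class(report) <- c("iso_report", "data.frame")
  report
}

# Fit each replicate tank separately and average; SE = between-tank spread.
fit_replicates <- function(dobs, iso, diet, model, sw, ks) {
  reps <- unique(dobs$replicate)
  fits <- lapply(seq_along(reps), function(i) {
    s <- dobs[dobs$replicate == reps[i] & dobs$day >= sw, ]
    s <- s[order(s$day), ]
    if (model == "G") {
      wr <- weight_ratios(s, sw)
      fit_model_g(wr$w_r, s[[iso]], isotope = iso, diet = diet)
    } else {
      fit_model_d(s$day - sw, s[[iso]], k = ks[i], isotope = iso, diet = diet)
    }
  })
  cf <- sapply(fits, function(f) f$coefficients)
  avg <- fits[[1]]
  avg$coefficients[] <- rowMeans(cf)
  avg$se[] <- apply(cf, 1, stats::sd) / sqrt(length(fits))
  avg$r2 <- mean(vapply(fits, function(f) f$r2, numeric(1)))
  avg$converged <- all(vapply(fits, function(f) f$converged, logical(1)))
  avg$flags <- unique(unlist(lapply(fits, function(f) f$flags)))
  avg
}

report_row <- function(diet, iso, model, fit, k, delta_diet, alphas,
                       curve) {
  base <- data.frame(diet_group = diet, isotope = iso, model = model,
                     stringsAsFactors = FALSE)
  if (inherits(fit, "error") || !is.finite(fit$coefficients[[1]]) ||
      !is.finite(fit$coefficients[[rate_name_chr(model)]])) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit)
           else paste(fit$flags, collapse = "; ")
    return(cbind(base, data.frame(
      delta_eq = NA_real_, se_delta_eq = NA_real_, a = NA_real_,
      rate = NA_real_, se_rate = NA_real_, k = k, r2 = NA_real_,
      g50 = NA_real_, g95 = NA_real_, d50 = NA_real_, d95 = NA_real_,
      p_g = NA_real_, p_m = NA_real_, delta_delta = NA_real_,
      converged = FALSE, note = msg)))
  }
  cf <- fit$coefficients
  rn <- rate_name_chr(model)
  if (model == "G") {
    g <- turnover_weight_fold(cf[[rn]], alphas)
    d <- suppressWarnings(
      convert_turnover_scale(curve, g, "weight_to_days"))
  } else {
    d <- turnover_days(cf[[rn]], k, alphas)
    g <- suppressWarnings(
      convert_turnover_scale(curve, d, "days_to_weight"))
  }
  part <- partition_turnover(max(1, g[1]))
  cbind(base, data.frame(
    delta_eq = cf[["delta_eq"]], se_delta_eq = fit$se[["delta_eq"]],
    a = cf[["a"]], rate = cf[[rn]], se_rate = fit$se[[rn]], k = k,
    r2 = fit$r2,
    g50 = g[1], g95 = g[2], d50 = d[1], d95 = d[2],
    p_g = part[["p_g"]], p_m = part[["p_m"]],
    delta_delta = discrimination_factor(cf[["delta_eq"]], delta_diet),
    converged = fit$converged,
    note = paste(fit$flags, collapse = "; ")))
}

rate_name_chr <- function(model) if (model == "G") "c" else "m"

discrimination_table <- function(report) {
  keys <- unique(report[, c("diet_group", "isotope")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- report$diet_group == keys$diet_group[i] &
      report$isotope == keys$isotope[i] & is.finite(report$delta_delta)
    dd <- report$delta_delta[sel]
    data.frame(diet_group = keys$diet_group[i], isotope = keys$isotope[i],
               n_models = length(dd),
               dd_mean = if (length(dd)) mean(dd) else NA_real_,
               dd_sd = if (length(dd) >= 2) stats::sd(dd) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-model average discrimination factors
#'
#' Arithmetic mean and standard deviation of the per-model discrimination
#' factors for each diet group and isotope. With a single available model
#' the mean is that model's value and the sd is `NA` (flagged in
#' `n_models`).
#'
#' @param report an `iso_report` from [run_analysis()], or any data.frame
#'   with columns `diet_group`, `isotope`, `delta_delta`.
#' @return data.frame with columns `diet_group`, `isotope`, `n_models`,
#'   `dd_mean`, `dd_sd`.
#' @export
average_discrimination <- function(report) {
  stopifnot(all(c("diet_group", "isotope", "delta_delta") %in% names(report)))
  discrimination_table(report)
}

#' @export
print.iso_report <- function(x, digits = 1, ...) {
  cat("Diet-switch isotope incorporation report\n")
  cat(sprintf("Prey baseline: %s (d13C %.2f, d15N %.2f permil)\n",
              attr(x, "prey_baseline")$prey,
              attr(x, "prey_baseline")$d13C, attr(x, "prey_baseline")$d15N))
  show <- as.data.frame(x)
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], function(v)
    ifelse(abs(v) < 1 & v != 0, signif(v, 3), round(v, digits)))
  show$rate <- round(x$rate, 3)
  show$k <- round(x$k, 4)
  show$note <- NULL
  print(show)
  cat("\nCross-model discrimination averages (permil):\n")
  avg <- attr(x, "discrimination_averages")
  avg$dd_mean <- round(avg$dd_mean, digits)
  avg$dd_sd <- round(avg$dd_sd, digits)
  print(avg)
  invisible(x)
}

#' Write / read an analysis report
#'
#' Full-precision CSV serialization of the report table and its
#' discrimination-average attribute; `read_report()` restores both, so the
#' round trip is lossless.
#'
#' @param report an `iso_report`.
#' @param path path of the report CSV; the averages go to a sidecar file
#'   `*_discrimination.csv`.
#' @return `read_report()` returns the `iso_report`.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, na = "")
  utils::write.csv(
    format(attr(report, "discrimination_averages"), digits = 17,
           scientific = FALSE, trim = TRUE),
    sidecar_path(path), row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  avg <- if (file.exists(sidecar_path(path)))
    utils::read.csv(sidecar_path(path), stringsAsFactors = FALSE)
  attr(df, "discrimination_averages") <- avg
  class(df) <- c("iso_report", "data.frame")
  df
}

sidecar_path <- function(path)
  sub("(\\.[^.]*)?$", "_discrimination\\1", path)

#' Recompute the reference derived turnover columns
#'
#' Rebuilds every derived column (turnover on the model's native scale,
#' partition, discrimination) from the reference printed parameters
#' ([hreidi_kinetics()]), the growth rates implied by the reference
#' endpoint dry weights ([hreidi_weights()]) and the curve prey baseline.
#' Used as a consistency check that the package algebra reproduces the
#' reference trial's report.
#'
#' @param alphas turnover percentages.
#' @return data.frame: the kinetics table plus recomputed `g50`, `g95`,
#'   `d50`, `d95`, `p_g`, `p_m`, `delta_delta`. Native-scale columns only:
#'   `g50/g95` are `NA` for model D rows and `d50/d95` for model G rows
#'   (the trial's cross-scale transformation is not reproducible from
#'   printed summaries).
#' @export
reproduce_reference <- function(alphas = c(50, 95)) {
  kin <- hreidi_kinetics()
  w <- hreidi_weights()
  prey <- hreidi_prey()
  base <- prey[prey$prey == "artemia_curve", ]
  k <- vapply(c(A6 = "A6", A11 = "A11"), function(d) {
    s <- w[w$diet_group == d, ]
    growth_rate_k(s$dw_mg[which.min(s$day)], s$dw_mg[which.max(s$day)],
                  max(s$day) - min(s$day))
  }, numeric(1))
  derived <- do.call(rbind, lapply(seq_len(nrow(kin)), function(i) {
    row <- kin[i, ]
    dm <- derive_turnover_metrics(row$model, row$delta_eq, row$rate,
                                  k = k[[row$diet_group]],
                                  delta_diet = base[[row$isotope]],
                                  alphas = alphas)
    if (row$model == "G") dm[c("d50", "d95")] <- NA_real_
    else dm[c("g50", "g95")] <- NA_real_
    dm
  }))
  cbind(kin, k = k[kin$diet_group], derived)
}
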