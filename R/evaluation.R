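## Replication harness: runs the six analysis methods over replicated
## cohorts, computes the performance metrics against the truth oracle, and
## writes machine-readable reports.

.all_methods <- c("AN", "CN", "A2S", "ARI", "C2S", "CSt")
.additive_methods <- c("AN", "A2S", "ARI")

#' Censor a cohort at the end of a follow-up year
#'
#' @param cohort A `haziv_cohort` data frame.
#' @param y Year end (0 < y <= the cohort's censoring horizon).
#' @return The cohort with `time = pmin(time, y)` and events after `y`
#'   recoded as censored.
#' @export
censor_at_year <- function(cohort, y) {
  stopifnot(y > 0)
  ev <- as.integer(cohort$event == 1 & cohort$time <= y)
  cohort$event <- ev
  cohort$time <- pmin(cohort$time, y)
  cohort
}

.fit_one_method <- function(method, cohort, fs, cst_nboot) {
  switch(method,
    AN = fit_additive_naive(cohort),
    CN = fit_cox_naive(cohort),
    A2S = fit_additive_two_stage(cohort, fs),
    ARI = fit_additive_2sri(cohort, fs),
    C2S = fit_cox_two_stage(cohort, fs),
    CSt = fit_structural_cox(cohort, nboot = cst_nboot),
    stop("unknown method: ", method))
}

.extract_row <- function(method, fit) {
  if (inherits(fit, "haziv_structural_coxfit")) {
    est <- fit$theta
    se <- fit$se
    lo <- fit$ci[1]; hi <- fit$ci[2]
    flag <- if (fit$no_solution) "no_solution" else ""
  } else {
    k <- fit$trt_col
    est <- unname(fit$theta[k])
    se <- unname(fit$se[k])
    lo <- est - 1.959964 * se
    hi <- est + 1.959964 * se
    flag <- if (!is.null(fit$n_negative_increments) &&
                fit$n_negative_increments > 0) "negative_increments" else ""
  }
  data.frame(method = method,
             scale = if (method %in% .additive_methods) "HD" else "logHR",
             estimate = est, se = se, lo = lo, hi = hi, flag = flag)
}

.predict_one <- function(method, fit, x_set, t) {
  if (method %in% .additive_methods)
    predict_survival_additive(fit, x_set, t)
  else if (method %in% c("CN", "C2S"))
    predict_survival_cox(fit, x_set, t)
  else NULL  # CSt has no survival-prediction machinery
}

#' Run one simulation scenario
#'
#' For each replicate: simulate an observational cohort, fit the first
#' stage once, then fit each requested method on the cohort censored at
#' each requested year; standardised per-arm survival predictions at years
#' `1..tau_max` are taken from the full-horizon fits.  Replicate seeds are
#' derived from `(seed, replicate)` with [substream_seed()], so any single
#' replicate is reproducible in isolation and results do not depend on
#' execution order.  Failed fits are captured as flagged rows, never
#' dropped silently.
#'
#' @param spec A [scenario_spec()].
#' @param methods Subset of `c("AN","CN","A2S","ARI","C2S","CSt")`.
#' @param n_reps Number of replicated cohorts.
#' @param n Cohort size (defaults to `spec$n`).
#' @param seed Master integer seed.
#' @param years Analysis years for the hazard-contrast fits (default: the
#'   full horizon only).
#' @param pred_years Years at which survival predictions are recorded
#'   (default `1:tau_max`); `NULL` disables predictions.
#' @param cst_nboot Bootstrap resamples for the structural-Cox SE inside
#'   the harness; default 0 (point estimates only -- the full 200-resample
#'   bootstrap is desk-scale prohibitive across replicates and is logged
#'   as disabled).
#' @return Object of class `haziv_simresult`: list with data frames
#'   `estimates` (`rep, year, method, scale, estimate, se, lo, hi, flag`)
#'   and `survival` (`rep, method, arm, year, pred, n_invalid`), plus the
#'   run configuration in `config`.
#' @export
run_scenario <- function(spec, methods = .all_methods, n_reps = 10,
                         n = spec$n, seed = 1L, years = NULL,
                         pred_years = seq_len(floor(spec$tau_max)),
                         cst_nboot = 0L) {
  stopifnot(inherits(spec, "haziv_scenario"),
            all(methods %in% .all_methods))
  coeffs <- lookup_coefficients(spec)
  if (is.null(years)) years <- spec$tau_max
  est_rows <- list(); surv_rows <- list()
  for (r in seq_len(n_reps)) {
    cohort <- simulate_observational_cohort(
      spec, coeffs, n = n, seed = substream_seed(seed, 1L, r))
    fs <- if (any(methods %in% c("A2S", "ARI", "C2S")))
      tryCatch(fit_treatment_model(cohort), error = function(e) e)
    else NULL
    for (m in methods) {
      needs_fs <- m %in% c("A2S", "ARI", "C2S")
      if (needs_fs && inherits(fs, "error")) {
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          rep = r, year = NA_real_, method = m, scale = NA_character_,
          estimate = NA_real_, se = NA_real_, lo = NA_real_, hi = NA_real_,
          flag = paste0("first_stage_error: ", conditionMessage(fs)))
        next
      }
      for (y in years) {
        cy <- if (y >= spec$tau_max) cohort else censor_at_year(cohort, y)
        fit <- tryCatch(.fit_one_method(m, cy, fs, cst_nboot),
                        error = function(e) e)
        row <- if (inherits(fit, "error")) {
          data.frame(method = m, scale = NA_character_,
                     estimate = NA_real_, se = NA_real_,
                     lo = NA_real_, hi = NA_real_,
                     flag = paste0("fit_error: ", conditionMessage(fit)))
        } else .extract_row(m, fit)
        row <- cbind(data.frame(rep = r, year = y), row)
        est_rows[[length(est_rows) + 1L]] <- row
        if (!is.null(pred_years) && y >= spec$tau_max &&
            !inherits(fit, "error")) {
          for (arm in c(0L, 1L)) for (py in pred_years) {
            pr <- .predict_one(m, fit, arm, py)
            if (is.null(pr)) next
            surv_rows[[length(surv_rows) + 1L]] <- data.frame(
              rep = r, method = m, arm = arm, year = py,
              pred = pr$survival, n_invalid = pr$n_invalid)
          }
        }
      }
    }
  }
  structure(list(
    estimates = do.call(rbind, est_rows),
    survival = if (length(surv_rows)) do.call(rbind, surv_rows) else NULL,
    config = list(spec = spec, coeffs = coeffs, methods = methods,
                  n_reps = n_reps, n = n, seed = seed, years = years,
                  pred_years = pred_years, cst_nboot = cst_nboot)
  ), class = "haziv_simresult")
}

#' @export
print.haziv_simresult <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<haziv_simresult> %d replicates x n = %d, methods: %s\n",
              cfg$n_reps, cfg$n, paste(cfg$methods, collapse = ", ")))
  nf <- sum(nzchar(x$estimates$flag))
  if (nf > 0) cat(sprintf("  %d flagged rows\n", nf))
  invisible(x)
}

.truth_column <- function(scale, target) {
  if (scale == "HD") {
    switch(target, marginal = "hd_marginal", conditional = "hd_conditional",
           ett = stop("no ETT hazard difference is defined here"))
  } else {
    switch(target, marginal = "hr_marginal", conditional = "hr_conditional",
           ett = "ett_hr")
  }
}

#' Performance metrics against the truth oracle
#'
#' Per method and year: mean estimate, MC SE (the SD across replicates),
#' bias, relative bias (%), MSE (`var + bias^2`), coverage (%) and power
#' (%).  Additive methods are compared to the hazard difference and Cox
#' methods to the hazard ratio of the chosen target; Cox estimates and
#' their Wald confidence limits are transformed from the log scale to the
#' HR scale for bias/MSE/coverage, while power keeps the estimation scale
#' (CI excluding 0 log-HR or 0 HD).  Flagged or failed replicates are
#' excluded from the summaries with their count reported.
#'
#' @param result A [run_scenario()] result.
#' @param truth A `haziv_truth` table covering the analysis years.
#' @param target `"marginal"`, `"conditional"` or `"ett"` (the latter only
#'   for Cox-scale methods).
#' @return Object of class `haziv_metrics` (a data frame).
#' @export
compute_metrics <- function(result, truth, target = "marginal") {
  stopifnot(inherits(result, "haziv_simresult"))
  est <- result$estimates
  rows <- list()
  for (m in unique(est$method)) {
    for (y in unique(est$year[est$method == m & !is.na(est$year)])) {
      sub <- est[est$method == m & !is.na(est$year) & est$year == y, ]
      scale <- if (m %in% .additive_methods) "HD" else "logHR"
      tc <- .truth_column(scale, target)
      trow <- truth[truth$year == y, ]
      if (nrow(trow) != 1 || is.null(trow[[tc]]) || is.na(trow[[tc]]))
        stop(sprintf("truth value `%s` missing for year %g", tc, y))
      theta_true <- trow[[tc]]
      ok <- !nzchar(sub$flag) & is.finite(sub$estimate)
      n_fail <- sum(!ok)
      sub <- sub[ok, ]
      if (scale == "logHR") {
        val <- exp(sub$estimate)
        lo <- exp(sub$lo); hi <- exp(sub$hi)
        null_covered <- sub$lo <= 0 & sub$hi >= 0
      } else {
        val <- sub$estimate
        lo <- sub$lo; hi <- sub$hi
        null_covered <- lo <= 0 & hi >= 0
      }
      mean_est <- mean(val)
      bias <- mean_est - theta_true
      mc_se <- sd(val)
      have_ci <- is.finite(lo) & is.finite(hi)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, year = y, target = target, scale = scale,
        truth = theta_true, n_used = nrow(sub), n_fail = n_fail,
        mean_estimate = mean_est, mc_se = mc_se,
        mean_se = sd(val) / sqrt(nrow(sub)),
        bias = bias,
        rel_bias_pct = 100 * bias / theta_true,
        mse = stats::var(val) * (nrow(sub) - 1) / nrow(sub) + bias^2,
        coverage_pct = if (any(have_ci))
          100 * mean(lo[have_ci] <= theta_true &
                     hi[have_ci] >= theta_true) else NA_real_,
        power_pct = if (any(have_ci))
          100 * mean(!null_covered[have_ci]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("haziv_metrics", "data.frame")
  out
}

#' Survival-prediction error summaries
#'
#' Mean, SD, minimum and maximum of (predicted - true) survival per
#' method, arm and year, plus the count of subject-level predictions
#' outside [0, 1] (kept unclipped in the raw tables).
#'
#' @param result A [run_scenario()] result with survival predictions.
#' @param truth A `haziv_truth` table with `S1`, `S0` per year.
#' @return Data frame with columns `method, arm, year, mean_err, sd_err,
#'   min_err, max_err, n_invalid`.
#' @export
survival_prediction_error <- function(result, truth) {
  stopifnot(inherits(result, "haziv_simresult"))
  sv <- result$survival
  if (is.null(sv)) stop("result carries no survival predictions")
  rows <- list()
  for (m in unique(sv$method)) for (arm in c(0L, 1L)) {
    for (y in sort(unique(sv$year))) {
      sub <- sv[sv$method == m & sv$arm == arm & sv$year == y, ]
      if (nrow(sub) == 0) next
      tr <- truth[truth$year == y, if (arm == 1) "S1" else "S0"]
      err <- sub$pred - tr
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, arm = arm, year = y,
        mean_err = mean(err), sd_err = if (nrow(sub) > 1) sd(err) else 0,
        min_err = min(err), max_err = max(err),
        n_invalid = sum(sub$n_invalid))
    }
  }
  do.call(rbind, rows)
}

#' Write simulation artefacts as delimited text
#'
#' Writes the per-replicate estimates, survival predictions, metrics table
#' and a run log (seed, scenario, package version, recorded decisions)
#' under `destination` with fixed column order and fixed float formatting,
#' so re-running on the same inputs is byte-identical.
#'
#' @param result A [run_scenario()] result.
#' @param metrics Optional [compute_metrics()] table.
#' @param destination Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report <- function(result, metrics = NULL, destination) {
  if (!dir.exists(destination))
    dir.create(destination, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(z) sprintf("%.10g", z))
    df
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(destination, name)
    if (is.null(df) || nrow(df) == 0) {
      warning("empty table: ", name)
      df <- df[0, , drop = FALSE]
    }
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$estimates, "estimates.csv")
  if (!is.null(result$survival)) wr(result$survival, "survival.csv")
  if (!is.null(metrics)) wr(as.data.frame(metrics), "metrics.csv")
  cfg <- result$config
  log_lines <- c(
    sprintf("package: hazivsim %s",
            as.character(utils::packageVersion("hazivsim"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("n_reps: %d  n: %d", cfg$n_reps, cfg$n),
    sprintf("methods: %s", paste(cfg$methods, collapse = ",")),
    sprintf("scenario: %s / %s / %s / effect=%s / iv=%s / conf=%s",
            cfg$spec$dgm_form, cfg$spec$baseline, cfg$spec$survival_level,
            cfg$spec$effect_size, cfg$spec$iv_strength,
            cfg$spec$confounding),
    sprintf("cst_bootstrap_resamples: %d (0 = SEs not run in harness)",
            cfg$cst_nboot),
    "ci_type: Wald on the estimation scale (sandwich SEs)")
  p <- file.path(destination, "run_log.txt")
  writeLines(log_lines, p)
  invisible(c(paths, p))
}
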