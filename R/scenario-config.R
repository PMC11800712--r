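#' Scenario specification for the simulation grid
#'
#' A scenario fixes the data-generating mechanism (DGM) form, the baseline
#' hazard family, the 5-year reference-group survival level, and the labelled
#' magnitudes of treatment effect, instrument strength and unmeasured
#' confounding.  The full grid crosses 3 baselines x 2 survival levels x
#' 3 effects x 4 instrument strengths x 3 confounding levels x 2 DGM forms
#' (432 scenarios).
#'
#' @param dgm_form `"additive"` or `"multiplicative"`.
#' @param baseline `"exponential"`, `"weibull_decreasing"` (shape 0.5) or
#'   `"weibull_increasing"` (shape 1.5).
#' @param survival_level `"high"` (reference-group S(5) = 0.60) or `"low"`
#'   (S(5) = 0.30).
#' @param effect_size `"small"`, `"medium"` or `"large"`.
#' @param iv_strength `"very_weak"`, `"weak"`, `"moderate"` or `"strong"`.
#' @param confounding `"weak"`, `"moderate"` or `"strong"`.
#' @param tau_max Administrative follow-up horizon in years.
#' @param n Default cohort size for simulation runs.
#' @return An object of class `haziv_scenario`.
#' @export
scenario_spec <- function(dgm_form = c("additive", "multiplicative"),
                          baseline = c("exponential", "weibull_decreasing",
                                       "weibull_increasing"),
                          survival_level = c("low", "high"),
                          effect_size = c("small", "medium", "large"),
                          iv_strength = c("very_weak", "weak", "moderate",
                                          "strong"),
                          confounding = c("weak", "moderate", "strong"),
                          tau_max = 5, n = 10000L) {
  dgm_form <- match.arg(dgm_form)
  baseline <- match.arg(baseline)
  survival_level <- match.arg(survival_level)
  effect_size <- match.arg(effect_size)
  iv_strength <- match.arg(iv_strength)
  confounding <- match.arg(confounding)
  if (!is.numeric(tau_max) || tau_max <= 0)
    stop("`tau_max` must be a positive number of years")
  if (!is.numeric(n) || n < 2)
    stop("`n` must be at least 2")
  structure(list(
    dgm_form = dgm_form,
    baseline = baseline,
    gamma = .baseline_shape(baseline),
    survival_level = survival_level,
    s_target = if (survival_level == "high") 0.60 else 0.30,
    effect_size = effect_size,
    iv_strength = iv_strength,
    confounding = confounding,
    tau_max = tau_max,
    n = as.integer(n)
  ), class = "haziv_scenario")
}

.baseline_shape <- function(baseline) {
  switch(baseline,
         exponential = 1,
         weibull_decreasing = 0.5,
         weibull_increasing = 1.5,
         stop("unknown baseline family: ", baseline))
}

#' @export
print.haziv_scenario <- function(x, ...) {
  cat(sprintf(
    "<haziv_scenario> %s DGM, %s baseline (shape %.1f), S(%g)=%.2f\n",
    x$dgm_form, x$baseline, x$gamma, x$tau_max, x$s_target))
  cat(sprintf("  effect: %s | IV: %s | confounding: %s | n = %d\n",
              x$effect_size, x$iv_strength, x$confounding, x$n))
  invisible(x)
}

#' Multiplicative-scale calibration of the baseline scale parameter
#'
#' Solves for the Weibull/exponential scale `lambda` so that the
#' reference-group survival (linear predictor zero) at the follow-up horizon
#' equals the target: `S0(tau) = exp(-lambda * tau^gamma) = S_target`, giving
#' `lambda = -log(S_target) / tau^gamma` in closed form.
#'
#' @param s_target Target reference-group survival probability at `tau`.
#' @param gamma Baseline shape (1 = exponential).
#' @param tau Follow-up horizon in years.
#' @return The scale parameter (events per year^gamma).
#' @export
solve_scale_multiplicative <- function(s_target, gamma, tau) {
  if (!is.numeric(s_target) || s_target <= 0 || s_target >= 1)
    stop("`s_target` must lie strictly between 0 and 1")
  if (gamma <= 0 || tau <= 0)
    stop("`gamma` and `tau` must be positive")
  -log(s_target) / tau^gamma
}

#' Additive-scale baseline parameter
#'
#' The additive DGM uses one tenth of the multiplicative scale,
#' `lambda_A = 0.1 * lambda_M`; the remaining calibration is absorbed by the
#' additive intercept and the time rescaling (see [solve_time_rescaling()]).
#'
#' @param lambda_m Multiplicative-DGM scale parameter.
#' @return The additive-DGM scale parameter.
#' @export
derive_additive_scale <- function(lambda_m) {
  if (!is.numeric(lambda_m) || lambda_m <= 0)
    stop("`lambda_m` must be positive")
  0.1 * lambda_m
}

## Fixed coefficient grids.  Treatment-model coefficients are on the probit
## scale; outcome coefficients are hazard differences per year (additive) or
## log hazard ratios (multiplicative).
.effect_grid <- list(
  multiplicative = c(small = -0.1, medium = -0.2, large = -0.4),
  additive       = c(small = -0.035, medium = -0.07, large = -0.13))
.iv_grid <- c(very_weak = 0.1, weak = 0.3, moderate = 0.5, strong = 0.8)
.confounding_grid <- list(
  multiplicative = list(weak     = c(aCU = -0.1, bCU = 0.1),
                        moderate = c(aCU = -0.3, bCU = 0.3),
                        strong   = c(aCU = -0.5, bCU = 0.5)),
  additive       = list(weak     = c(aCU = -0.1, bCU = 0.01),
                        moderate = c(aCU = -0.3, bCU = 0.04),
                        strong   = c(aCU = -0.5, bCU = 0.05)))
.fixed_outcome <- list(
  multiplicative = c(b0 = 0, bCM = 0.2),
  additive       = c(b0 = 0.4, bCM = 0.02))

#' Resolve the numeric coefficient set for a scenario
#'
#' Maps the labelled scenario levels to the fixed coefficient grids and
#' calibrates the baseline scale (and, for additive scenarios, the follow-up
#' restriction and time-rescaling factor).  Treatment assignment is always
#' probit with `alpha0 = 0`, `alphaCM = -0.2`.
#'
#' @param spec A [scenario_spec()].
#' @param calibration Calibration strategy for the additive time rescaling;
#'   only `"reference_survival"` is built in, but a function
#'   `(coeffs, s_target, tau_max) -> list(tau_restrict, c)` may be supplied.
#' @return An object of class `haziv_coefs` with elements `alpha`
#'   (`a0, aZ, aCM, aCU`), `beta` (`b0, bX, bCM, bCU`), `lambda`, `gamma`,
#'   `tau_restrict` and `time_rescale`.
#' @export
lookup_coefficients <- function(spec, calibration = "reference_survival") {
  stopifnot(inherits(spec, "haziv_scenario"))
  form <- spec$dgm_form
  conf <- .confounding_grid[[form]][[spec$confounding]]
  beta <- c(.fixed_outcome[[form]]["b0"],
            bX = unname(.effect_grid[[form]][spec$effect_size]),
            .fixed_outcome[[form]]["bCM"],
            bCU = unname(conf["bCU"]))
  alpha <- c(a0 = 0, aZ = unname(.iv_grid[spec$iv_strength]),
             aCM = -0.2, aCU = unname(conf["aCU"]))
  lambda_m <- solve_scale_multiplicative(spec$s_target, spec$gamma,
                                         spec$tau_max)
  coeffs <- structure(list(
    alpha = alpha, beta = beta,
    lambda = if (form == "additive") derive_additive_scale(lambda_m)
             else lambda_m,
    gamma = spec$gamma,
    dgm_form = form,
    tau_restrict = spec$tau_max,
    time_rescale = 1
  ), class = "haziv_coefs")
  if (form == "additive") {
    cal <- if (is.function(calibration)) {
      calibration(coeffs, spec$s_target, spec$tau_max)
    } else if (identical(calibration, "reference_survival")) {
      solve_time_rescaling(coeffs, spec$s_target, spec$tau_max)
    } else stop("unknown calibration strategy: ", calibration)
    coeffs$tau_restrict <- cal$tau_restrict
    coeffs$time_rescale <- cal$time_rescale
  }
  coeffs
}

#' @export
print.haziv_coefs <- function(x, ...) {
  cat(sprintf("<haziv_coefs> %s DGM, shape %.1f, scale %.4g\n",
              x$dgm_form, x$gamma, x$lambda))
  cat("  alpha:", paste(names(x$alpha), sprintf("%.3g", x$alpha),
                        sep = "=", collapse = " "), "\n")
  cat("  beta: ", paste(names(x$beta), sprintf("%.3g", x$beta),
                        sep = "=", collapse = " "), "\n")
  if (x$time_rescale != 1)
    cat(sprintf("  follow-up restricted to %.4g y, times rescaled by %.4g\n",
                x$tau_restrict, x$time_rescale))
  invisible(x)
}

#' Additive-DGM follow-up restriction and time rescaling
#'
#' The additive hazard grows much faster than its multiplicative counterpart,
#' so event times are simulated on a restricted horizon `tau_restrict` chosen
#' so that the reference group (all covariates zero, untreated) has survival
#' `s_target` at `tau_restrict`; simulated times are then multiplied by
#' `c = tau_max / tau_restrict` so the follow-up length matches.
#' `tau_restrict` solves the reference cumulative hazard equation
#' `lambda * t^gamma + b0 * t = -log(s_target)`: closed form for the
#' exponential baseline, a bracketed 1-D root solve for Weibull shapes.
#'
#' @param coeffs A `haziv_coefs` for an additive scenario.
#' @param s_target Target reference-group survival at `tau_max`.
#' @param tau_max Nominal follow-up horizon (years).
#' @param tol Root-solver tolerance on `tau_restrict`.
#' @return List with `tau_restrict` (years) and `time_rescale` (`c >= 1`
#'   whenever restriction was needed).
#' @export
solve_time_rescaling <- function(coeffs, s_target, tau_max, tol = 1e-10) {
  stopifnot(inherits(coeffs, "haziv_coefs"))
  if (coeffs$dgm_form != "additive")
    stop("time rescaling applies to additive scenarios only")
  lam <- coeffs$lambda; gam <- coeffs$gamma; b0 <- coeffs$beta[["b0"]]
  target <- -log(s_target)
  cumhaz <- function(t) lam * t^gam + b0 * t
  tau_restrict <- if (gam == 1) {
    target / (lam + b0)
  } else {
    upper <- tau_max
    while (cumhaz(upper) < target) upper <- upper * 2
    stats::uniroot(function(t) cumhaz(t) - target,
                   lower = 0, upper = upper, tol = tol)$root
  }
  if (!is.finite(tau_restrict) || tau_restrict <= 0)
    stop("calibration failed: no positive root for the reference horizon")
  list(tau_restrict = tau_restrict, time_rescale = tau_max / tau_restrict)
}

#' Enumerate the full scenario grid
#'
#' @param tau_max Follow-up horizon in years.
#' @param n Default cohort size attached to each scenario.
#' @return List of [scenario_spec()] objects in deterministic order
#'   (DGM form slowest, then baseline, survival level, effect, IV strength,
#'   confounding fastest); the full grid has 432 entries.
#' @export
enumerate_scenarios <- function(tau_max = 5, n = 10000L) {
  grid <- expand.grid(
    confounding = c("weak", "moderate", "strong"),
    iv_strength = c("very_weak", "weak", "moderate", "strong"),
    effect_size = c("small", "medium", "large"),
    survival_level = c("low", "high"),
    baseline = c("exponential", "weibull_decreasing", "weibull_increasing"),
    dgm_form = c("additive", "multiplicative"),
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    scenario_spec(dgm_form = g$dgm_form, baseline = g$baseline,
                  survival_level = g$survival_level,
                  effect_size = g$effect_size, iv_strength = g$iv_strength,
                  confounding = g$confounding, tau_max = tau_max, n = n)
  })
}

#' Scenario manifest as a data frame
#'
#' Resolves every scenario in a grid to its numeric parameters, one row per
#' scenario -- the tabular form consumed by the `calibrate` command-line
#' subcommand.
#'
#' @param scenarios List of scenarios, e.g. from [enumerate_scenarios()].
#' @return A data frame with the label columns and all resolved numeric
#'   parameters.
#' @export
scenario_manifest <- function(scenarios = enumerate_scenarios()) {
  rows <- lapply(seq_along(scenarios), function(i) {
    sp <- scenarios[[i]]
    cf <- lookup_coefficients(sp)
    data.frame(scenario_id = i, dgm_form = sp$dgm_form,
               baseline = sp$baseline, gamma = cf$gamma,
               survival_level = sp$survival_level, s_target = sp$s_target,
               effect_size = sp$effect_size, iv_strength = sp$iv_strength,
               confounding = sp$confounding, tau_max = sp$tau_max, n = sp$n,
               a0 = cf$alpha[["a0"]], aZ = cf$alpha[["aZ"]],
               aCM = cf$alpha[["aCM"]], aCU = cf$alpha[["aCU"]],
               b0 = cf$beta[["b0"]], bX = cf$beta[["bX"]],
               bCM = cf$beta[["bCM"]], bCU = cf$beta[["bCU"]],
               lambda = cf$lambda, tau_restrict = cf$tau_restrict,
               time_rescale = cf$time_rescale)
  })
  do.call(rbind, rows)
}
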