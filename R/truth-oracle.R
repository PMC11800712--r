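## Monte-Carlo oracle for the true causal estimands of a scenario: the
## marginal, conditional-on-CM and treated-subgroup (ETT) hazard contrasts
## and the true per-arm survival probabilities, all evaluated on a simulated
## ideal RCT (full compliance, no censoring before the analysis year).

#' True marginal (and optionally conditional) causal contrasts
#'
#' Simulates one huge randomised cohort under the scenario's DGM and, for
#' each follow-up year, censors at the year end and fits an unadjusted Cox
#' model (marginal hazard ratio), an unadjusted additive-hazards model
#' (marginal hazard difference) and per-arm Kaplan-Meier curves (true
#' survival probabilities).  With `conditional = TRUE` the Cox and additive
#' models are refitted with `CM` to give the conditional contrasts.
#' Standard errors of the huge-cohort fits are reported as the MC
#' uncertainty of each truth value.
#'
#' @param spec A [scenario_spec()].
#' @param coeffs Calibrated coefficients (looked up when omitted).
#' @param n_mc Monte-Carlo cohort size (default 2,000,000; a warning below
#'   1e6, an error below 1e4).
#' @param seed Integer seed.
#' @param years Follow-up years at which the contrasts are evaluated.
#' @param conditional Also compute the conditional-on-CM contrasts.
#' @return Object of class `haziv_truth`: a data frame with one row per
#'   year and columns `hr_marginal`, `hr_marginal_se`, `hd_marginal`,
#'   `hd_marginal_se`, `S1`, `S0` (and the conditional analogues when
#'   requested), plus attributes `n_mc` and `spec`.
#' @export
true_marginal_contrasts <- function(spec, coeffs = NULL, n_mc = 2e6,
                                    seed = NULL, years = 1:5,
                                    conditional = FALSE) {
  stopifnot(inherits(spec, "haziv_scenario"))
  if (n_mc < 1e4) stop("`n_mc` below 1e4 gives a meaningless truth oracle")
  if (n_mc < 1e6)
    warning("`n_mc` below 1e6: truth values carry visible MC error")
  if (is.null(coeffs)) coeffs <- lookup_coefficients(spec)
  rct <- simulate_rct_cohort(spec, coeffs, n = n_mc, seed = seed,
                             censor = FALSE)
  tl <- rct$t_latent
  rows <- lapply(years, function(y) {
    tm <- pmin(tl, y)
    ev <- as.integer(tl <= y)
    cx <- fit_cox_binary_fast(tm, ev, rct$X)
    ad <- fit_additive_constant(tm, ev, cbind(X = rct$X))
    trt <- rct$X == 1
    out <- data.frame(
      year = y,
      hr_marginal = exp(cx$theta), hr_marginal_se = exp(cx$theta) * cx$se,
      hd_marginal = unname(ad$theta["X"]),
      hd_marginal_se = unname(ad$se["X"]),
      S1 = km_survival(tm[trt], ev[trt], y),
      S0 = km_survival(tm[!trt], ev[!trt], y))
    if (conditional) {
      cxc <- fit_cox(tm, ev, cbind(X = rct$X, CM = rct$CM))
      adc <- fit_additive_constant(tm, ev, cbind(X = rct$X, CM = rct$CM))
      out$hr_conditional <- exp(unname(cxc$theta["X"]))
      out$hr_conditional_se <- out$hr_conditional * unname(cxc$se["X"])
      out$hd_conditional <- unname(adc$theta["X"])
      out$hd_conditional_se <- unname(adc$se["X"])
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "n_mc") <- n_mc
  attr(out, "spec") <- spec
  class(out) <- c("haziv_truth", "data.frame")
  out
}

#' True conditional-on-CM contrasts
#'
#' Convenience wrapper for [true_marginal_contrasts()] with
#' `conditional = TRUE`.
#'
#' @inheritParams true_marginal_contrasts
#' @return See [true_marginal_contrasts()].
#' @export
true_conditional_contrasts <- function(spec, coeffs = NULL, n_mc = 2e6,
                                       seed = NULL, years = 1:5) {
  true_marginal_contrasts(spec, coeffs, n_mc, seed, years,
                          conditional = TRUE)
}

#' True hazard ratio of treatment in the treated (ETT)
#'
#' Reconstructs the treated-subgroup estimand by simulating the
#' observational treatment assignment, generating both potential event
#' times for every treated subject from the outcome model with shared
#' covariates and a shared uniform draw, and fitting an unadjusted Cox
#' model to the stacked counterfactual data, censored at each analysis
#' year.  The shared draw makes the construction rank-preserving within
#' the simulator (a diagnostic property, not an extra assumption on the
#' estimand).
#'
#' @inheritParams true_marginal_contrasts
#' @return Data frame with columns `year`, `ett_hr`, `ett_hr_se`,
#'   `n_treated`.
#' @export
true_ett <- function(spec, coeffs = NULL, n_mc = 2e6, seed = NULL,
                     years = 1:5) {
  stopifnot(inherits(spec, "haziv_scenario"))
  if (is.null(coeffs)) coeffs <- lookup_coefficients(spec)
  if (!is.null(seed)) set.seed(seed)
  cov <- simulate_covariates(n_mc)
  X <- assign_treatment_probit(cov$Z, cov$CM, cov$CU, coeffs$alpha)
  treated <- which(X == 1)
  if (length(treated) == 0) stop("treated subgroup is empty")
  cm <- cov$CM[treated]; cu <- cov$CU[treated]
  u <- stats::runif(length(treated))
  lp1 <- .cohort_linpred(coeffs$beta, 1, cm, cu)
  lp0 <- .cohort_linpred(coeffs$beta, 0, cm, cu)
  t1 <- .latent_from_u(lp1, coeffs, u)
  t0 <- .latent_from_u(lp0, coeffs, u)
  tl <- c(t1, t0)
  arm <- rep(c(1L, 0L), each = length(treated))
  rows <- lapply(years, function(y) {
    tm <- pmin(tl, y)
    ev <- as.integer(tl <= y)
    cx <- fit_cox_binary_fast(tm, ev, arm)
    data.frame(year = y, ett_hr = exp(cx$theta),
               ett_hr_se = exp(cx$theta) * cx$se,
               n_treated = length(treated))
  })
  do.call(rbind, rows)
}

#' Full truth table for a scenario
#'
#' Combines [true_marginal_contrasts()] (with conditional contrasts) and
#' [true_ett()] into one per-year table -- the output of the `truth`
#' command-line subcommand.
#'
#' @inheritParams true_marginal_contrasts
#' @return A `haziv_truth` data frame with marginal, conditional, ETT and
#'   survival columns.
#' @export
true_causal_estimands <- function(spec, coeffs = NULL, n_mc = 2e6,
                                  seed = NULL, years = 1:5) {
  if (is.null(coeffs)) coeffs <- lookup_coefficients(spec)
  marg <- true_marginal_contrasts(spec, coeffs, n_mc, seed, years,
                                  conditional = TRUE)
  ett <- true_ett(spec, coeffs, n_mc,
                  if (is.null(seed)) NULL else substream_seed(seed, 777L),
                  years)
  out <- merge(as.data.frame(marg), ett, by = "year")
  attr(out, "n_mc") <- n_mc
  attr(out, "spec") <- spec
  class(out) <- c("haziv_truth", "data.frame")
  out
}
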