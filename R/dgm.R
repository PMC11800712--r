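## Data-generating mechanisms: covariates, probit treatment, event times
## under additive or multiplicative hazards, administrative censoring.

#' Derive a reproducible substream seed
#'
#' Expands one master seed into independent per-task seeds with a
#' counter-based integer hash, so replicates and scenarios are reproducible
#' in isolation and insensitive to execution order.  Result is kept in
#' [0, 2^31 - 1).
#'
#' @param seed Master integer seed.
#' @param ... Further integer counters (scenario id, replicate index, ...).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    # multiplicative LCG step (Park-Miller modulus) mixed with the counter
    x <- (x * 48271 + as.double(k) * 2246822519 + 374761393) %% 2147483647
  }
  as.integer(x)
}

#' Simulate instrument and confounders
#'
#' Binary instrument Z ~ Bernoulli(0.5); measured confounder CM and
#' unmeasured confounder CU independent standard normal.
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed (set before drawing when supplied).
#' @return A data frame with columns `Z`, `CM`, `CU`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  data.frame(Z = stats::rbinom(n, 1L, 0.5),
             CM = stats::rnorm(n),
             CU = stats::rnorm(n))
}

#' Probit treatment assignment
#'
#' Each subject is treated with probability
#' `pnorm(a0 + aZ*Z + aCM*CM + aCU*CU)`.
#'
#' @param Z,CM,CU Covariate vectors of equal length.
#' @param alpha Named vector `c(a0, aZ, aCM, aCU)` on the probit scale.
#' @return Integer 0/1 treatment vector.
#' @export
assign_treatment_probit <- function(Z, CM, CU, alpha) {
  stopifnot(length(Z) == length(CM), length(CM) == length(CU))
  p <- stats::pnorm(alpha[["a0"]] + alpha[["aZ"]] * Z +
                    alpha[["aCM"]] * CM + alpha[["aCU"]] * CU)
  stats::rbinom(length(Z), 1L, p)
}

#' Invert the cumulative hazard to an event time
#'
#' Multiplicative DGM: `H(t) = lambda * t^gamma * exp(lp)`, inverted in
#' closed form.  Additive DGM: `H(t) = lambda * t^gamma + lp * t`; closed
#' form when `gamma = 1`, otherwise solved by monotone vectorised bisection
#' (the hazard must be positive along the solution path, which makes `H`
#' strictly increasing there).  Subjects whose cumulative hazard at
#' `horizon` never reaches `-log(u)` are returned as `Inf` (they survive
#' past the follow-up window); this can only occur for the additive form
#' when a `horizon` is given.
#'
#' @param lp Linear-predictor vector `W'beta`.
#' @param lambda,gamma Baseline scale and shape.
#' @param form `"additive"` or `"multiplicative"`.
#' @param u Uniform(0,1) draws, one per subject.
#' @param horizon Additive form only: solve on `[0, horizon]`, returning
#'   `Inf` beyond it.  `NULL` expands the bracket until it contains the root.
#' @param tol Absolute bisection tolerance for the additive Weibull case.
#' @return Vector of event times.
#' @export
simulate_event_time <- function(lp, lambda, gamma, form, u,
                                horizon = NULL, tol = 1e-12) {
  stopifnot(all(u > 0 & u < 1), lambda > 0, gamma > 0)
  y <- -log(u)
  if (form == "multiplicative")
    return((y / (lambda * exp(lp)))^(1 / gamma))
  if (form != "additive") stop("unknown DGM form: ", form)

  ## additive: check hazard positivity over the solution interval
  hmin <- if (gamma >= 1) lambda * gamma * .Machine$double.eps + lp
          else if (is.null(horizon)) lp
          else lambda * gamma * horizon^(gamma - 1) + lp
  ## gamma >= 1: hazard is minimal at t -> 0 (equals lp for gamma > 1,
  ## lambda + lp for gamma = 1); gamma < 1: minimal at the right end.
  if (gamma == 1) hmin <- lambda + lp
  n_bad <- sum(hmin <= 0)
  if (n_bad > 0)
    stop(sprintf(paste0("additive hazard non-positive for %d of %d subjects",
                        " (min linear predictor %.4g); the scenario needs",
                        " re-calibration"),
                 n_bad, length(y), min(lp)))
  if (gamma == 1) return(y / (lambda + lp))

  cumhaz <- function(t) lambda * t^gamma + lp * t
  if (is.null(horizon)) {
    hi <- rep(1, length(y))
    for (it in 1:200) {
      need <- cumhaz(hi) < y
      if (!any(need)) break
      hi[need] <- hi[need] * 2
    }
    alive <- rep(TRUE, length(y))
  } else {
    hi <- rep(horizon, length(y))
    alive <- cumhaz(hi) >= y
  }
  t_out <- rep(Inf, length(y))
  lo <- numeric(length(y))
  idx <- which(alive)
  if (length(idx)) {
    lo_a <- lo[idx]; hi_a <- hi[idx]; y_a <- y[idx]; lp_a <- lp[idx]
    for (it in 1:100) {
      mid <- (lo_a + hi_a) / 2
      below <- (lambda * mid^gamma + lp_a * mid) < y_a
      lo_a[below] <- mid[below]
      hi_a[!below] <- mid[!below]
      if (max(hi_a - lo_a) < tol) break
    }
    t_out[idx] <- (lo_a + hi_a) / 2
  }
  t_out
}

#' Administrative censoring
#'
#' @param t_latent Latent event times (may contain `Inf`).
#' @param tau_max Censoring horizon in years.
#' @return List with observed `time = pmin(t_latent, tau_max)` and integer
#'   `event = 1{t_latent <= tau_max}` (an event exactly at the horizon
#'   counts as observed).
#' @export
apply_administrative_censoring <- function(t_latent, tau_max) {
  stopifnot(all(t_latent > 0), tau_max > 0)
  list(time = pmin(t_latent, tau_max),
       event = as.integer(t_latent <= tau_max))
}

.cohort_linpred <- function(beta, X, CM, CU) {
  beta[["b0"]] + beta[["bX"]] * X + beta[["bCM"]] * CM + beta[["bCU"]] * CU
}

.finish_cohort <- function(cov, X, t_latent, tau_max, keep_latent) {
  cens <- apply_administrative_censoring(t_latent, tau_max)
  out <- data.frame(id = seq_along(X), Z = cov$Z, CM = cov$CM, CU = cov$CU,
                    X = X, time = cens$time, event = cens$event)
  if (keep_latent) out$t_latent <- t_latent
  class(out) <- c("haziv_cohort", "data.frame")
  out
}

#' Simulate an observational cohort
#'
#' Covariates, probit-confounded treatment, event times from the scenario's
#' hazard model (additive times are generated on the restricted horizon and
#' rescaled by `time_rescale`), then administrative censoring at `tau_max`.
#'
#' @param spec A [scenario_spec()].
#' @param coeffs Calibrated coefficients from [lookup_coefficients()]
#'   (looked up from `spec` when omitted).
#' @param n Cohort size (defaults to `spec$n`).
#' @param seed Integer seed.
#' @param keep_latent Keep the pre-censoring latent time as a column.
#' @return A `haziv_cohort` data frame with columns
#'   `id, Z, CM, CU, X, time, event`.
#' @export
simulate_observational_cohort <- function(spec, coeffs = NULL, n = spec$n,
                                          seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(spec, "haziv_scenario"))
  if (is.null(coeffs)) coeffs <- lookup_coefficients(spec)
  if (!is.null(seed)) set.seed(seed)
  cov <- simulate_covariates(n)
  X <- assign_treatment_probit(cov$Z, cov$CM, cov$CU, coeffs$alpha)
  t_latent <- .simulate_latent_times(cov, X, spec, coeffs)
  .finish_cohort(cov, X, t_latent, spec$tau_max, keep_latent)
}

#' Simulate a randomised cohort (ideal RCT)
#'
#' As [simulate_observational_cohort()] but treatment is assigned at random,
#' independently of instrument and confounders; by default there is no
#' informative structure between `X` and `(Z, CM, CU)`.  Administrative
#' censoring is still applied at `tau_max` (pass `censor = FALSE` to keep
#' latent times beyond the horizon flagged as censored-at-horizon with the
#' latent column retained).
#'
#' @inheritParams simulate_observational_cohort
#' @param p_treat Randomisation probability of treatment.
#' @param censor Apply administrative censoring at `tau_max` (the latent
#'   time is always retained when `censor = FALSE`).
#' @return A `haziv_cohort` data frame.
#' @export
simulate_rct_cohort <- function(spec, coeffs = NULL, n = spec$n, seed = NULL,
                                p_treat = 0.5, keep_latent = FALSE,
                                censor = TRUE) {
  stopifnot(inherits(spec, "haziv_scenario"))
  if (p_treat <= 0 || p_treat >= 1)
    stop("`p_treat` must lie strictly between 0 and 1")
  if (is.null(coeffs)) coeffs <- lookup_coefficients(spec)
  if (!is.null(seed)) set.seed(seed)
  cov <- simulate_covariates(n)
  X <- stats::rbinom(n, 1L, p_treat)
  t_latent <- .simulate_latent_times(cov, X, spec, coeffs)
  .finish_cohort(cov, X, t_latent, spec$tau_max,
                 keep_latent || !censor)
}

## Latent event times for a cohort under the scenario's DGM; additive times
## are solved on the restricted horizon and rescaled so effects and
## follow-up live on the nominal time axis.
.simulate_latent_times <- function(cov, X, spec, coeffs) {
  lp <- .cohort_linpred(coeffs$beta, X, cov$CM, cov$CU)
  .latent_from_u(lp, coeffs, stats::runif(length(X)))
}

## Latent time from a supplied uniform draw (shared-u counterfactual
## construction in the truth oracle reuses this with both treatment arms).
.latent_from_u <- function(lp, coeffs, u) {
  if (coeffs$dgm_form == "multiplicative") {
    simulate_event_time(lp, coeffs$lambda, coeffs$gamma, "multiplicative", u)
  } else {
    t0 <- simulate_event_time(lp, coeffs$lambda, coeffs$gamma, "additive", u,
                              horizon = coeffs$tau_restrict)
    t0 * coeffs$time_rescale
  }
}
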