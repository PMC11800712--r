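## Cox-side analysis models: naive Cox (CN), two-stage Cox IV (C2S) and the
## structural Cox g-estimator of the effect of treatment in the treated
## (CSt), plus Breslow-based standardised survival prediction.

#' Cox proportional-hazards fit with Breslow baseline
#'
#' Thin wrapper around [survival::coxph()] with Breslow tie handling
#' (needed for consistency between the partial likelihood and the baseline
#' hazard estimator), returning the coefficient vector, covariance and the
#' Breslow cumulative baseline hazard step function.
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param W Covariate matrix (or vector).
#' @return An object of class `haziv_coxfit`: `theta` (log hazard ratios),
#'   `se`, `vcov`, `utime`/`cumhaz` (Breslow baseline at the event times),
#'   `loglik`, `n`, `nevent`.
#' @export
fit_cox <- function(time, event, W) {
  W <- as.matrix(W)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  if (sum(event) < 1) stop("no events observed; Cox fit undefined")
  const <- apply(W, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(W)[const], collapse = ", "))
  df <- data.frame(.time = time, .event = event)
  df <- cbind(df, as.data.frame(W))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(colnames(W), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  if (any(!is.finite(coef(fit))) || any(!is.finite(sqrt(diag(vcov(fit))))))
    stop("Cox partial likelihood degenerate (monotone likelihood?)")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    theta = coef(fit), se = sqrt(diag(vcov(fit))), vcov = vcov(fit),
    utime = bh$time, cumhaz = bh$hazard,
    loglik = fit$loglik[length(fit$loglik)],
    n = length(time), nevent = sum(event), w_names = colnames(W)
  ), class = "haziv_coxfit")
}

#' @export
print.haziv_coxfit <- function(x, ...) {
  cat(sprintf("<haziv_coxfit> n = %d, events = %d (Breslow ties)\n",
              x$n, x$nevent))
  print(data.frame(coef = x$theta, HR = exp(x$theta), se = x$se))
  invisible(x)
}

#' Naive Cox model (CN)
#'
#' Cox regression of the outcome on observed treatment and the measured
#' confounder; the treatment coefficient is a conditional (on CM) log
#' hazard ratio only if CM sufficed to control confounding.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @return A `haziv_coxfit`.
#' @export
fit_cox_naive <- function(cohort) {
  fit <- fit_cox(cohort$time, cohort$event,
                 cbind(X = cohort$X, CM = cohort$CM))
  fit$method <- "CN"
  fit$trt_col <- "X"
  fit$frame <- cbind(X = cohort$X, CM = cohort$CM)
  fit
}

#' Two-stage Cox IV model (C2S)
#'
#' Cox regression on the first-stage treatment prediction `Xhat` and `CM`.
#' Because of the non-linearity of the Cox model the treatment coefficient
#' is not a causal effect measure; the caveat travels with the fit.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @param first_stage A [fit_treatment_model()] result for `cohort`.
#' @return A `haziv_coxfit` with `$caveat` set.
#' @export
fit_cox_two_stage <- function(cohort, first_stage) {
  stopifnot(inherits(first_stage, "haziv_first_stage"))
  W <- cbind(Xhat = first_stage$fitted, CM = cohort$CM)
  fit <- fit_cox(cohort$time, cohort$event, W)
  fit$method <- "C2S"
  fit$trt_col <- "Xhat"
  fit$caveat <- .method_caveats[["C2S"]]
  fit$frame <- W
  fit
}

#' Closed-form split of the linearised structural-Cox equation
#'
#' For binary treatment and centred instrument function
#' `g_i = g(Z_i) - mean(g(Z))`, the linearised g-estimation equation
#' `sum_i g_i * S_i * exp(-theta * X_i) = 0` splits into
#' `A + B exp(-theta) = 0` with `A = sum_{X=0} g_i S_i`,
#' `B = sum_{X=1} g_i S_i`, so `theta = -log(-A/B)` whenever `-A/B > 0`.
#' This is the small-cumulative-hazard linearisation of the structural
#' model's survival relation `S_{T0} = S^{exp(-theta)}` among the treated;
#' [fit_structural_cox()] solves the exact power-form equation
#' `sum_i g_i * S_i^{exp(-theta * X_i)} = 0` and uses this split only for
#' diagnostics and bracketing.
#'
#' @param g Centred instrument values (must average to ~0).
#' @param S Estimated `P(T_i > t | X_i, Z_i)` per subject.
#' @param X 0/1 treatment vector.
#' @return List with `theta` and the split sums `A`, `B`; `theta` is `NA`
#'   with `no_solution = TRUE` when the equation has no root.
#' @export
solve_structural_cox <- function(g, S, X) {
  stopifnot(length(g) == length(S), length(S) == length(X))
  A <- sum(g[X == 0] * S[X == 0])
  B <- sum(g[X == 1] * S[X == 1])
  ratio <- -A / B
  if (!is.finite(ratio) || ratio <= 0)
    return(list(theta = NA_real_, A = A, B = B, no_solution = TRUE))
  list(theta = -log(ratio), A = A, B = B, no_solution = FALSE)
}

#' Solve the structural-Cox power-form estimating equation
#'
#' Finds `psi = exp(-theta)` solving
#' `sum_{X=0} g_i S_i + sum_{X=1} g_i S_i^psi = 0` by bracketed
#' root-finding; under the structural Cox model `S^psi` is the treated
#' subjects' counterfactual untreated survival, so `exp(theta) = 1/psi` is
#' the hazard ratio of treatment in the treated.
#'
#' @inheritParams solve_structural_cox
#' @param bracket Search interval for `psi`.
#' @return List with `theta`, `psi` and `no_solution` (no sign change over
#'   the bracket).
#' @export
solve_structural_cox_power <- function(g, S, X, bracket = c(1e-8, 1e8)) {
  stopifnot(length(g) == length(S), length(S) == length(X))
  A <- sum(g[X == 0] * S[X == 0])
  g1 <- g[X == 1]; S1 <- S[X == 1]
  f <- function(psi) A + sum(g1 * S1^psi)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    return(list(theta = NA_real_, psi = NA_real_, no_solution = TRUE))
  psi <- stats::uniroot(f, bracket, tol = 1e-12)$root
  list(theta = -log(psi), psi = psi, no_solution = FALSE)
}

#' Structural Cox IV model (CSt)
#'
#' G-estimation of the structural Cox model for the effect of treatment in
#' the treated: the hazard ratio `exp(thetaX)` contrasts the treated
#' subjects' factual hazard with their counterfactual untreated hazard.
#' The nuisance survival probabilities `P(T_i > t_eval | X_i, Z_i)` come
#' from a Cox model on `(X, Z)` (optionally plus `CM`, or with an `X:Z`
#' interaction), and the estimating equation
#' `sum_i g_i S_i^{exp(-theta X_i)} = 0` uses `g(Z) = Z - mean(Z)` by
#' default.  The equation can genuinely fail to have a solution (no sign
#' change over the search bracket), which is reported, not patched.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @param t_eval Evaluation time; defaults to the largest observed time
#'   (the administrative horizon of the analysis dataset).
#' @param g Function of the instrument vector; centred internally.
#' @param adjust_cm Include `CM` in the nuisance Cox model.
#' @param interaction Include an `X:Z` interaction in the nuisance model.
#' @param nboot Nonparametric bootstrap resamples for the SE (percentile
#'   CI); `0` skips the bootstrap (SE is `NA`).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `haziv_structural_coxfit`: `theta` (ETT log
#'   hazard ratio), `se`, `ci`, `t_eval`, `no_solution`, `nuisance`
#'   (the underlying `haziv_coxfit`), `n_boot_failed`.
#' @export
fit_structural_cox <- function(cohort, t_eval = max(cohort$time),
                               g = function(z) z, adjust_cm = FALSE,
                               interaction = FALSE, nboot = 200L,
                               seed = NULL) {
  if (length(unique(cohort$Z)) < 2)
    stop("instrument Z is constant; g-estimation impossible")
  if (length(unique(cohort$X)) < 2)
    stop("both treatment groups must be non-empty")

  point <- .structural_cox_once(cohort, t_eval, g, adjust_cm, interaction)
  se <- NA_real_; ci <- c(NA_real_, NA_real_); n_boot_failed <- 0L
  if (nboot > 0 && !point$no_solution) {
    if (!is.null(seed)) set.seed(seed)
    est <- numeric(0)
    for (bb in seq_len(nboot)) {
      idx <- sample.int(nrow(cohort), replace = TRUE)
      bs <- tryCatch(
        .structural_cox_once(cohort[idx, , drop = FALSE], t_eval, g,
                             adjust_cm, interaction),
        error = function(e) list(theta = NA_real_, no_solution = TRUE))
      if (bs$no_solution) n_boot_failed <- n_boot_failed + 1L
      else est <- c(est, bs$theta)
    }
    if (length(est) >= 2) {
      se <- sd(est)
      ci <- unname(stats::quantile(est, c(0.025, 0.975)))
    }
  }
  structure(list(
    theta = point$theta, se = se, ci = ci, t_eval = t_eval,
    no_solution = point$no_solution, A = point$A, B = point$B,
    g_description = "g(Z) centred at the sample mean",
    nuisance = point$nuisance, nboot = nboot,
    n_boot_failed = n_boot_failed
  ), class = "haziv_structural_coxfit")
}

.structural_cox_once <- function(cohort, t_eval, g, adjust_cm,
                                 interaction) {
  W <- cbind(X = cohort$X, Z = cohort$Z)
  if (interaction) W <- cbind(W, XZ = cohort$X * cohort$Z)
  if (adjust_cm) W <- cbind(W, CM = cohort$CM)
  nuis <- fit_cox(cohort$time, cohort$event, W)
  H0 <- .cox_cumhaz_at(nuis, t_eval)
  S <- exp(-H0 * exp(drop(W %*% nuis$theta)))
  gz <- g(cohort$Z)
  gz <- gz - mean(gz)
  sol <- solve_structural_cox_power(gz, S, cohort$X)
  lin <- solve_structural_cox(gz, S, cohort$X)
  c(sol, list(A = lin$A, B = lin$B, nuisance = nuis))
}

#' @export
print.haziv_structural_coxfit <- function(x, ...) {
  cat(sprintf("<haziv_structural_coxfit> t_eval = %g\n", x$t_eval))
  if (x$no_solution) {
    cat("  estimating equation has no solution (-A/B <= 0)\n")
  } else {
    cat(sprintf("  ETT log HR = %.4f (HR %.4f), bootstrap se = %s\n",
                x$theta, exp(x$theta),
                ifelse(is.na(x$se), "not run", sprintf("%.4f", x$se))))
  }
  invisible(x)
}

.cox_cumhaz_at <- function(fit, t) {
  if (t > max(fit$utime) + 1e-12)
    stop(sprintf("prediction time %g beyond last event time %g",
                 t, max(fit$utime)))
  idx <- findInterval(t, fit$utime)
  if (idx == 0) 0 else fit$cumhaz[idx]
}

#' Standardised survival prediction from a Cox fit
#'
#' Per-subject survival `exp(-H0(t) exp(theta' W_i))` with the treatment
#' column set to `x_set`, averaged over the analysis sample (Breslow
#' baseline, marginalisation over the empirical covariate distribution).
#'
#' @param fit A `haziv_coxfit` from one of the cohort-level wrappers.
#' @param x_set Treatment arm, 0 or 1.
#' @param t Prediction time in years.
#' @return List with `survival` and `n_invalid` (always 0 for the Cox
#'   model, reported for schema symmetry with the additive side).
#' @export
predict_survival_cox <- function(fit, x_set, t) {
  stopifnot(inherits(fit, "haziv_coxfit"), x_set %in% c(0, 1))
  if (is.null(fit$frame))
    stop("fit carries no design matrix; use the cohort-level wrappers")
  W <- fit$frame
  W[, fit$trt_col] <- x_set
  H0 <- .cox_cumhaz_at(fit, t)
  s <- exp(-H0 * exp(drop(W %*% fit$theta)))
  list(survival = mean(s), n_invalid = sum(s < 0 | s > 1))
}

#' Fast unadjusted Cox fit for a binary covariate
#'
#' Newton maximisation of the Breslow partial likelihood aggregated over
#' distinct event times, mathematically identical to [fit_cox()] with a
#' single binary covariate but orders of magnitude faster on the
#' million-subject cohorts used by the truth oracle.
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param x Binary covariate.
#' @return List with `theta` (log hazard ratio) and `se`.
#' @export
fit_cox_binary_fast <- function(time, event, x) {
  stopifnot(length(unique(x)) == 2, all(x %in% c(0, 1)))
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; x_s <- x[o]
  ut_first <- c(TRUE, t_s[-1] != t_s[-length(t_s)])
  idx <- which(ut_first)
  n <- length(t_s)
  n1_suffix <- rev(cumsum(rev(x_s)))
  nrisk <- n - idx + 1
  n1 <- n1_suffix[idx]
  n0 <- nrisk - n1
  grp <- cumsum(ut_first)
  d <- tabulate(grp[e_s == 1], nbins = length(idx))
  d1 <- tabulate(grp[e_s == 1 & x_s == 1], nbins = length(idx))
  keep <- d > 0
  n0 <- n0[keep]; n1 <- n1[keep]; d <- d[keep]; d1 <- d1[keep]
  beta <- 0
  for (it in 1:50) {
    eb <- exp(beta)
    denom <- n0 + n1 * eb
    score <- sum(d1) - sum(d * n1 * eb / denom)
    info <- sum(d * n0 * n1 * eb / denom^2)
    step <- score / info
    beta <- beta + step
    if (abs(step) < 1e-12) break
  }
  list(theta = beta, se = sqrt(1 / info))
}

#' Kaplan-Meier survival at given times
#'
#' Product-limit estimator evaluated at `at` (vectorised over distinct
#' event times; ties allowed).
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param at Evaluation times.
#' @return Survival probabilities at `at`.
#' @export
km_survival <- function(time, event, at) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  ut_first <- c(TRUE, t_s[-1] != t_s[-length(t_s)])
  idx <- which(ut_first)
  n <- length(t_s)
  nrisk <- n - idx + 1
  grp <- cumsum(ut_first)
  d <- tabulate(grp[e_s == 1], nbins = length(idx))
  keep <- d > 0
  ut <- t_s[idx][keep]
  surv <- cumprod(1 - d[keep] / nrisk[keep])
  pos <- findInterval(at, ut)
  c(1, surv)[pos + 1]
}
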