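## Additive-hazards analysis models: naive (AN), two-stage (A2S) and the
## two-stage residual-inclusion / control-function model (ARI), all built on
## one semiparametric estimating-equation engine.

#' Semiparametric additive-hazards fit
#'
#' Fits `h(t | V, W) = rho(t)' V + theta' W`, where the columns of `V`
#' receive unrestricted time-varying coefficients (the first column is the
#' baseline intercept unless supplied otherwise) and the columns of `W`
#' receive constant coefficients.  With `V` the intercept alone this is the
#' Lin-Ying constant-effects model: `theta` solves the least-squares
#' martingale estimating equation in which covariates are centred at the
#' risk-set mean, and the cumulative baseline hazard accumulates the
#' residual increments.  The time-varying block is profiled out by weighted
#' least squares on each risk set; integrals are discretised over the
#' distinct observed times (left-continuous risk sets, tied events share a
#' risk set).  Variance is the model-based sandwich with the
#' counting-process increments as variance numerator.
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param W Matrix (or vector) of constant-effect covariates.
#' @param V Matrix of time-varying-effect covariates; default intercept
#'   only.
#' @return An object of class `haziv_addfit`: `theta`, `se`, `vcov`,
#'   `utime`, `cumtv` (cumulative time-varying coefficient paths, one
#'   column per column of `V`; column 1 is the cumulative baseline hazard),
#'   `n`, `nevent`, and `n_negative_increments` (baseline-increment sign
#'   flags).
#' @export
fit_additive_constant <- function(time, event, W = NULL,
                                  V = matrix(1, length(time), 1,
                                             dimnames = list(NULL,
                                                             "baseline"))) {
  n <- length(time)
  if (sum(event) < 1) stop("no events observed; additive fit undefined")
  if (is.null(W)) return(.aalen_baseline_only(time, event))
  W <- as.matrix(W)
  V <- as.matrix(V)
  stopifnot(length(event) == n, nrow(W) == n, nrow(V) == n)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  if (is.null(colnames(V))) colnames(V) <- paste0("v", seq_len(ncol(V)))
  ## a constant column is absorbed by the baseline: no identification
  const <- apply(W, 2, function(col) max(col) - min(col) == 0)
  if (any(const))
    stop("constant-effect design rank deficient; collinear column(s): ",
         paste(colnames(W)[const], collapse = ", "))

  o <- order(time)
  eng <- additive_engine(time[o], as.integer(event[o]), V[o, , drop = FALSE],
                         W[o, , drop = FALSE])
  if (rcond(eng$A) < 1e-12)
    stop("constant-effect design rank deficient; collinear column(s): ",
         paste(colnames(W), collapse = ", "))
  qr_A <- qr(eng$A)
  if (qr_A$rank < ncol(W)) {
    bad <- colnames(W)[qr_A$pivot[seq(qr_A$rank + 1L, ncol(W))]]
    stop("constant-effect design rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  theta <- drop(solve(qr_A, eng$b))
  names(theta) <- colnames(W)
  A_inv <- solve(qr_A, diag(ncol(W)))
  vc <- A_inv %*% eng$B %*% t(A_inv)
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(W), colnames(W))

  ## cumulative time-varying paths: dR_k = Q1_k - Q2_k theta
  qv <- ncol(V)
  Theta <- matrix(0, qv * ncol(W), qv)
  for (m in seq_len(ncol(W)))
    Theta[cbind((m - 1L) * qv + seq_len(qv), seq_len(qv))] <- theta[m]
  dR <- eng$Q1 - eng$Q2 %*% Theta
  cumtv <- apply(dR, 2, cumsum)
  if (!is.matrix(cumtv)) cumtv <- matrix(cumtv, ncol = qv)
  colnames(cumtv) <- colnames(V)

  structure(list(
    theta = theta, se = sqrt(diag(vc)), vcov = vc,
    utime = eng$utime, cumtv = cumtv,
    nrisk = eng$nrisk, nevent_by_time = eng$nevent,
    n = n, nevent = sum(event),
    n_negative_increments = sum(dR[, 1] < 0),
    v_names = colnames(V), w_names = colnames(W)
  ), class = "haziv_addfit")
}

## Covariate-free limit: the cumulative baseline hazard is the
## Nelson-Aalen estimator.
.aalen_baseline_only <- function(time, event) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  ut_first <- c(TRUE, t_s[-1] != t_s[-length(t_s)])
  idx <- which(ut_first)
  n <- length(t_s)
  nrisk <- n - idx + 1
  grp <- cumsum(ut_first)
  d <- tabulate(grp[e_s == 1], nbins = length(idx))
  cum <- matrix(cumsum(d / nrisk), ncol = 1,
                dimnames = list(NULL, "baseline"))
  structure(list(
    theta = setNames(numeric(0), character(0)),
    se = numeric(0), vcov = matrix(0, 0, 0),
    utime = t_s[idx], cumtv = cum, nrisk = nrisk, nevent_by_time = d,
    n = n, nevent = sum(event),
    n_negative_increments = 0L,
    v_names = "baseline", w_names = character(0)
  ), class = "haziv_addfit")
}

#' @export
print.haziv_addfit <- function(x, ...) {
  cat(sprintf("<haziv_addfit> n = %d, events = %d\n", x$n, x$nevent))
  print(data.frame(coef = x$theta, se = x$se))
  if (length(x$v_names) > 1)
    cat("  time-varying terms:", paste(x$v_names, collapse = ", "), "\n")
  if (x$n_negative_increments > 0)
    cat(sprintf("  note: %d negative baseline-hazard increments\n",
                x$n_negative_increments))
  invisible(x)
}

.method_caveats <- c(
  A2S = "two-stage additive estimate; biased for the causal hazard difference when treatment is binary",
  C2S = "two-stage Cox coefficient; not a causal effect measure under a binary treatment")

#' Naive additive-hazards model (AN)
#'
#' Constant-effects additive regression of the outcome on observed
#' treatment and the measured confounder, ignoring unmeasured confounding.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @return A `haziv_addfit`; the treatment coefficient is a (confounded)
#'   marginal hazard difference per year.
#' @export
fit_additive_naive <- function(cohort) {
  fit <- fit_additive_constant(cohort$time, cohort$event,
                               cbind(X = cohort$X, CM = cohort$CM))
  fit$method <- "AN"
  fit$trt_col <- "X"
  fit$frame <- list(W = cbind(X = cohort$X, CM = cohort$CM),
                    V = matrix(1, nrow(cohort), 1,
                               dimnames = list(NULL, "baseline")))
  fit
}

#' Two-stage additive IV model (A2S)
#'
#' Replaces treatment by its first-stage prediction `Xhat` in a
#' constant-effects additive regression.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @param first_stage A [fit_treatment_model()] result for `cohort`.
#' @return A `haziv_addfit` carrying the documented binary-exposure caveat
#'   in `$caveat`.
#' @export
fit_additive_two_stage <- function(cohort, first_stage) {
  stopifnot(inherits(first_stage, "haziv_first_stage"))
  W <- cbind(Xhat = first_stage$fitted, CM = cohort$CM)
  fit <- fit_additive_constant(cohort$time, cohort$event, W)
  fit$method <- "A2S"
  fit$trt_col <- "Xhat"
  fit$caveat <- .method_caveats[["A2S"]]
  fit$frame <- list(W = W, V = matrix(1, nrow(cohort), 1,
                                      dimnames = list(NULL, "baseline")))
  fit
}

#' Two-stage residual-inclusion additive IV model (ARI)
#'
#' The control-function model
#' `h(t) = h0(t) + thetaX X + thetaCM CM + (rho0(t) + rho1(t) Z) Dhat`,
#' where `Dhat = X - P(X=1|Z,CM)` is the first-stage residual.  The
#' baseline and the two residual terms get unrestricted time-varying
#' coefficients; `thetaX` consistently estimates the marginal causal hazard
#' difference for a binary treatment when the additive model holds.
#'
#' @inheritParams fit_additive_two_stage
#' @return A `haziv_addfit` whose `cumtv` columns `Dhat` and `ZxDhat` are
#'   the cumulative control-function paths `R0(t)`, `R1(t)`.
#' @export
fit_additive_2sri <- function(cohort, first_stage) {
  stopifnot(inherits(first_stage, "haziv_first_stage"))
  W <- cbind(X = cohort$X, CM = cohort$CM)
  V <- cbind(baseline = rep(1, nrow(cohort)),
             Dhat = first_stage$residuals,
             ZxDhat = cohort$Z * first_stage$residuals)
  fit <- fit_additive_constant(cohort$time, cohort$event, W, V)
  fit$method <- "ARI"
  fit$trt_col <- "X"
  fit$frame <- list(W = W, V = V)
  fit
}

## Step-function lookup: value of the cumulative path at time t (0 before
## the first jump), plus an extrapolation guard.
.step_lookup <- function(utime, cum, t) {
  if (t > utime[length(utime)] + 1e-12)
    stop(sprintf("prediction time %g beyond last observed time %g",
                 t, utime[length(utime)]))
  idx <- findInterval(t, utime)
  if (idx == 0) rep(0, ncol(cum)) else cum[idx, ]
}

#' Standardised survival prediction from an additive fit
#'
#' For every subject the treatment column is set to `x_set` while all other
#' covariates (including, for the 2SRI model, the subject's own residual
#' and instrument terms) keep their observed values;
#' `S_i(t) = exp(-cum_tv(t)' V_i - theta' W_i t)` is averaged over the
#' analysis sample.  The additive model does not constrain `S_i(t)` to
#' [0, 1]; invalid per-subject values are counted and reported, never
#' clipped.
#'
#' @param fit A `haziv_addfit` produced by one of the cohort-level wrappers
#'   (it carries its design matrices).
#' @param x_set Treatment arm, 0 or 1.
#' @param t Prediction time (years), within the observed range.
#' @return List with `survival` (the standardised mean), `n_invalid`
#'   (subject-level predictions outside [0,1]) and `mean_unclipped`
#'   (identical to `survival`; retained to make the no-clipping contract
#'   explicit).
#' @export
predict_survival_additive <- function(fit, x_set, t) {
  stopifnot(inherits(fit, "haziv_addfit"), x_set %in% c(0, 1))
  if (length(fit$w_names) == 0) {
    s <- exp(-unname(.step_lookup(fit$utime, fit$cumtv, t)[1]))
    return(list(survival = s, n_invalid = as.integer(s < 0 || s > 1),
                mean_unclipped = s))
  }
  if (is.null(fit$frame))
    stop("fit carries no design matrices; use the cohort-level wrappers")
  W <- fit$frame$W
  W[, fit$trt_col] <- x_set
  V <- fit$frame$V
  cum_t <- .step_lookup(fit$utime, fit$cumtv, t)
  s <- exp(-(drop(V %*% cum_t) + drop(W %*% fit$theta) * t))
  n_invalid <- sum(s < 0 | s > 1)
  list(survival = mean(s), n_invalid = n_invalid, mean_unclipped = mean(s))
}
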