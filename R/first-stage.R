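#' First-stage treatment model
#'
#' Fits the logistic regression of treatment on instrument and measured
#' confounder, `logit P(X=1|Z,CM) = eta0 + etaZ*Z + etaCM*CM`, shared by all
#' two-stage IV methods.  Note the deliberate mismatch with the probit
#' data-generating model: the analysis stage never sees the true link.
#' Fitting is by iteratively reweighted least squares (via [stats::glm()])
#' with non-convergence treated as an error.
#'
#' @param cohort A `haziv_cohort` data frame (columns `X`, `Z`, `CM`).
#' @return An object of class `haziv_first_stage` with elements `eta`
#'   (coefficients), `fitted` (probabilities), `residuals` (`X - fitted`),
#'   `vcov` and `converged`.
#' @export
fit_treatment_model <- function(cohort) {
  if (length(unique(cohort$Z)) < 2)
    stop("instrument Z is constant; the first stage is not identified")
  if (length(unique(cohort$X)) < 2)
    stop("both treatment groups must be non-empty")
  fit <- stats::glm(X ~ Z + CM, family = stats::binomial(),
                    data = cohort,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  if (!fit$converged)
    stop("first-stage logistic regression did not converge")
  p <- unname(fit$fitted.values)
  if (any(p <= 1e-12) || any(p >= 1 - 1e-12))
    stop("first-stage fitted probabilities degenerate (separation?)")
  structure(list(
    eta = stats::coef(fit),
    fitted = p,
    residuals = cohort$X - p,
    vcov = stats::vcov(fit),
    converged = TRUE
  ), class = "haziv_first_stage")
}

#' @export
print.haziv_first_stage <- function(x, ...) {
  cat("<haziv_first_stage> logistic X ~ Z + CM\n")
  print(round(x$eta, 4))
  invisible(x)
}

#' Instrument-strength diagnostic
#'
#' The difference in the empirical probability of treatment between the two
#' instrument groups, `mean(X | Z=1) - mean(X | Z=0)`.  This is the
#' canonical strength report here; the first-stage F statistic is not used
#' because it scales with sample size for a binary exposure.
#'
#' @param cohort A `haziv_cohort` data frame.
#' @return List with `p1`, `p0` and `diff`.
#' @export
iv_strength_summary <- function(cohort) {
  n1 <- sum(cohort$Z == 1); n0 <- sum(cohort$Z == 0)
  if (n1 == 0 || n0 == 0)
    stop("an instrument group is empty; strength diagnostic undefined")
  p1 <- mean(cohort$X[cohort$Z == 1])
  p0 <- mean(cohort$X[cohort$Z == 0])
  list(p1 = p1, p0 = p0, diff = p1 - p0)
}
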