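# Shared fixtures and independent mini-oracles used across test files.

# Brute-force assembly of the constant-effects additive estimating equation
# over explicit risk sets (integrals discretised at the distinct observed
# times, risk set = {T >= t}); independent of the package's C++ engine.
brute_force_additive <- function(time, event, W) {
  W <- as.matrix(W)
  ut <- sort(unique(time))
  p <- ncol(W)
  A <- matrix(0, p, p)
  b <- numeric(p)
  prev <- 0
  for (tk in ut) {
    risk <- which(time >= tk)
    wbar <- colMeans(W[risk, , drop = FALSE])
    dt <- tk - prev
    prev <- tk
    for (i in risk) {
      d <- W[i, ] - wbar
      A <- A + dt * tcrossprod(d)
    }
    for (i in which(time == tk & event == 1)) {
      b <- b + (W[i, ] - wbar)
    }
  }
  solve(A, b)
}

# Breslow log partial likelihood and score for a single covariate, written
# directly from their definitions (independent of survival::coxph).
breslow_logpl <- function(beta, time, event, x) {
  ll <- 0
  for (tk in unique(time[event == 1])) {
    risk <- which(time >= tk)
    dead <- which(time == tk & event == 1)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

breslow_score <- function(beta, time, event, x) {
  sc <- 0
  for (tk in unique(time[event == 1])) {
    risk <- which(time >= tk)
    dead <- which(time == tk & event == 1)
    w <- exp(beta * x[risk])
    sc <- sc + sum(x[dead]) - length(dead) * sum(x[risk] * w) / sum(w)
  }
  sc
}

# Scalar bisection on a monotone function; oracle for the vectorised
# cumulative-hazard inversion.
bisect <- function(f, lo, hi, tol = 1e-12) {
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A first-stage object with constant fitted probabilities, for
# identification-failure tests.
constant_first_stage <- function(n, p = 0.5) {
  structure(list(eta = c(`(Intercept)` = stats::qlogis(p), Z = 0, CM = 0),
                 fitted = rep(p, n), residuals = rep(NA_real_, n),
                 vcov = matrix(0, 3, 3), converged = TRUE),
            class = "haziv_first_stage")
}
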