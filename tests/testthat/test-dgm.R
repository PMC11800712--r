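test_that("covariate simulation is reproducible and has the right laws", {
  a <- simulate_covariates(1000, seed = 42)
  b <- simulate_covariates(1000, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(simulate_covariates(1)), 1)
  expect_error(simulate_covariates(0), "at least 1")

  # law-of-large-numbers moments (n scaled down from the spec's 1e6 with
  # tolerances widened to > 6 binomial/normal SEs)
  big <- simulate_covariates(4e5, seed = 7)
  expect_lt(abs(mean(big$Z) - 0.5), 0.005)
  expect_lt(abs(sd(big$CM) - 1), 0.01)
  expect_lt(abs(mean(big$CU)), 0.01)
})

test_that("probit assignment matches the closed-form group probabilities", {
  # E[pnorm(a + b'W)] = pnorm(a / sqrt(1 + |b|^2)) for standard-normal W
  closed_diff <- function(aZ, aCM, aCU) {
    s <- sqrt(1 + aCM^2 + aCU^2)
    pnorm(aZ / s) - pnorm(0)
  }
  cov <- simulate_covariates(2e5, seed = 11)
  for (alpha in list(c(a0 = 0, aZ = 0.8, aCM = -0.2, aCU = -0.1),
                     c(a0 = 0, aZ = 0.1, aCM = -0.2, aCU = -0.1))) {
    set.seed(12)
    X <- assign_treatment_probit(cov$Z, cov$CM, cov$CU, alpha)
    diff <- mean(X[cov$Z == 1]) - mean(X[cov$Z == 0])
    expect_lt(abs(diff - closed_diff(alpha[["aZ"]], alpha[["aCM"]],
                                     alpha[["aCU"]])), 0.006)
  }
  # strong IV: about 28 percentage points; very weak: about 4
  expect_equal(round(100 * closed_diff(0.8, -0.2, -0.1)), 28)
  expect_equal(round(100 * closed_diff(0.1, -0.2, -0.1)), 4)

  set.seed(13)
  X0 <- assign_treatment_probit(cov$Z, cov$CM, cov$CU,
                                c(a0 = 0, aZ = 0, aCM = 0, aCU = 0))
  expect_lt(abs(mean(X0) - 0.5), 0.005)
})

test_that("event-time inversion matches closed forms and a bisection oracle", {
  lam <- 0.241
  expect_equal(simulate_event_time(0, lam, 1, "multiplicative",
                                   exp(-5 * lam)), 5)
  expect_equal(simulate_event_time(0.4, 0.0241, 1, "additive", 0.5),
               log(2) / 0.4241)
  # additive Weibull against scalar bisection on the cumulative hazard
  t_pkg <- simulate_event_time(0.4, 0.05384, 0.5, "additive", 0.5)
  t_orc <- bisect(function(t) 0.05384 * sqrt(t) + 0.4 * t - (-log(0.5)),
                  1e-8, 100)
  expect_equal(t_pkg, t_orc, tolerance = 1e-8)
  # non-positive additive hazard is an error, not a truncation
  expect_error(simulate_event_time(-0.3, 0.0241, 1, "additive", 0.5),
               "non-positive")
  expect_error(simulate_event_time(c(0.4, -0.5), 0.05, 0.5, "additive",
                                   c(0.5, 0.5), horizon = 5),
               "non-positive")
})

test_that("generated times follow the model survival function (KS check)", {
  n <- 2e4
  ks_crit <- 1.95 / sqrt(n)  # ~0.001-level Kolmogorov-Smirnov band
  set.seed(31)
  u <- runif(n)
  cases <- list(
    list(form = "multiplicative", lam = 0.241, gam = 1.0, lp = 0.3),
    list(form = "multiplicative", lam = 0.1077, gam = 1.5, lp = -0.4),
    list(form = "additive", lam = 0.0241, gam = 1.0, lp = 0.4),
    list(form = "additive", lam = 0.05384, gam = 0.5, lp = 0.4))
  for (cs in cases) {
    tt <- simulate_event_time(rep(cs$lp, n), cs$lam, cs$gam, cs$form, u)
    surv_true <- function(t) {
      if (cs$form == "multiplicative") exp(-cs$lam * t^cs$gam * exp(cs$lp))
      else exp(-(cs$lam * t^cs$gam + cs$lp * t))
    }
    grid <- quantile(tt, probs = seq(0.05, 0.95, by = 0.05))
    emp <- vapply(grid, function(g) mean(tt > g), numeric(1))
    expect_lt(max(abs(emp - surv_true(grid))), ks_crit)
  }
})

test_that("additive and multiplicative generators agree when gamma = 1 and lp = 0", {
  u <- runif(500, min = 1e-6, max = 1 - 1e-6)
  lam <- 0.241
  expect_equal(simulate_event_time(rep(0, 500), lam, 1, "additive", u),
               simulate_event_time(rep(0, 500), lam, 1, "multiplicative", u))
})

test_that("administrative censoring follows the boundary conventions", {
  expect_equal(apply_administrative_censoring(7, 5), list(time = 5, event = 0L))
  expect_equal(apply_administrative_censoring(3, 5), list(time = 3, event = 1L))
  expect_equal(apply_administrative_censoring(5, 5), list(time = 5, event = 1L))
  cc <- apply_administrative_censoring(rexp(100, 0.3), 5)
  expect_equal(sum(cc$event) + sum(cc$event == 0), 100)
})

test_that("cohort simulation is calibrated and deterministic", {
  for (form in c("multiplicative", "additive")) {
    sp <- scenario_spec(form, "exponential", "low", "large", "moderate",
                        "strong")
    cf <- lookup_coefficients(sp)
    # reference subjects (untreated, covariates zero): S(5) = 0.30
    set.seed(41)
    n <- 4e4
    lp <- cf$beta[["b0"]] * (form == "additive")
    tt <- if (form == "multiplicative") {
      simulate_event_time(rep(0, n), cf$lambda, cf$gamma, form, runif(n))
    } else {
      cf$time_rescale *
        simulate_event_time(rep(lp, n), cf$lambda, cf$gamma, form, runif(n),
                            horizon = cf$tau_restrict)
    }
    expect_lt(abs(mean(tt > 5 - 1e-9) - 0.30), 0.01)
  }

  sp <- scenario_spec("additive", "weibull_increasing", "high", "small",
                      "weak", "weak")
  c1 <- simulate_observational_cohort(sp, n = 10, seed = 99)
  c2 <- simulate_observational_cohort(sp, n = 10, seed = 99)
  expect_identical(c1, c2)
  expect_true(all(c1$time > 0))
  expect_true(all(c1$time[c1$event == 0] == sp$tau_max))
})

test_that("randomised cohorts break the treatment-confounder link", {
  sp <- scenario_spec("multiplicative", "exponential", "low", "large",
                      "strong", "strong")
  rct <- simulate_rct_cohort(sp, n = 2e5, seed = 5)
  expect_lt(abs(cor(rct$X, rct$CU)), 0.006)
  expect_lt(abs(cor(rct$X, rct$Z)), 0.006)
  expect_error(simulate_rct_cohort(sp, n = 100, p_treat = 1.2), "p_treat")

  # treated-arm survival under reference covariates: exp(-lam e^bX t)
  cf <- lookup_coefficients(sp)
  set.seed(6)
  n <- 4e4
  tt <- simulate_event_time(rep(cf$beta[["bX"]], n), cf$lambda, cf$gamma,
                            "multiplicative", runif(n))
  expect_lt(abs(mean(tt > 3) - exp(-cf$lambda * exp(cf$beta[["bX"]]) * 3)),
            0.01)

  # null effect: the two arms' Kaplan-Meier curves agree within MC error
  cf0 <- cf
  cf0$beta[["bX"]] <- 0
  rct0 <- simulate_rct_cohort(sp, cf0, n = 2e4, seed = 8)
  s1 <- km_survival(rct0$time[rct0$X == 1], rct0$event[rct0$X == 1], 4)
  s0 <- km_survival(rct0$time[rct0$X == 0], rct0$event[rct0$X == 0], 4)
  expect_lt(abs(s1 - s0), 0.02)
})
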