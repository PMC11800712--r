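---
title: "Instrumental-variable survival estimators under matched additive and multiplicative hazards: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IV survival simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the
data-generating mechanisms and their calibration, the six analysis
methods and the assumptions each one needs, the Monte-Carlo truth oracle,
the numerical conventions, and — importantly — what a green test
establishes and what it does not.

## 1. The stated world

Every simulated cohort lives in the same stylised epidemiological world:

* a binary instrument `Z ~ Bernoulli(0.5)` — think of a dichotomised risk
  score or a prescribing-preference indicator;
* a measured confounder `CM ~ N(0,1)` and an unmeasured confounder
  `CU ~ N(0,1)`, independent of each other and of `Z`;
* probit treatment assignment
  `P(X=1|Z,CM,CU) = pnorm(a0 + aZ*Z + aCM*CM + aCU*CU)` with `a0 = 0`,
  `aCM = -0.2` everywhere;
* event times from either an additive hazard
  `h(t) = h0(t) + W'beta` or a multiplicative hazard
  `h(t) = h0(t) exp(W'beta)` with `W'beta = b0 + bX*X + bCM*CM + bCU*CU`;
* an exponential (`h0 = lambda`) or Weibull (`h0 = lambda*gamma*t^(gamma-1)`,
  `gamma` 0.5 or 1.5) baseline;
* administrative censoring at `tau_max = 5` years and nothing else.

The labelled levels map to fixed numbers (units: probit scale for `alpha`;
per-year hazard for additive `beta`; log hazard ratio for multiplicative
`beta`):

* effect size `bX`: multiplicative −0.1/−0.2/−0.4; additive
  −0.035/−0.07/−0.13 (small/medium/large);
* instrument strength `aZ`: 0.1/0.3/0.5/0.8, i.e. treatment-probability
  differences between instrument groups of roughly 4 to 28 percentage
  points (the package reports this difference, not a first-stage F
  statistic, which grows with `n` for a binary exposure);
* confounding `(aCU, bCU)`: multiplicative (−0.1,0.1)/(−0.3,0.3)/(−0.5,0.5);
  additive (−0.1,0.01)/(−0.3,0.04)/(−0.5,0.05);
* intercepts `b0`, `bCM`: multiplicative 0 and 0.2; additive 0.4 and 0.02.

These defaults *are* the stated world: they were not chosen by this
package and are not tuned by it. The full grid (2 DGM forms × 3 baselines
× 2 survival levels × 3 effects × 4 instrument strengths × 3 confounding
levels) has 432 scenarios, enumerated in a fixed order by
`enumerate_scenarios()`.

## 2. Calibration: matching the two hazard scales

The multiplicative scale parameter is closed-form:
`lambda_M = -log(S_target)/tau^gamma` makes the reference group
(`W'beta = 0`) hit survival `S_target` (0.60 or 0.30) at 5 years exactly.

Additive hazards grow much faster in these parameterisations, so the
additive scenarios use `lambda_A = 0.1*lambda_M` plus a **time
rescaling**: event times are simulated on a restricted horizon
`tau_restrict` solving the reference-group cumulative-hazard equation

```
lambda_A * t^gamma + b0 * t = -log(S_target)
```

(closed form for the exponential baseline; a bracketed `uniroot` to 1e-10
for Weibull shapes), then multiplied by `c = tau_max/tau_restrict`. After
rescaling, reference-group survival at 5 years again equals `S_target`,
and every additive hazard coefficient acts, effectively, divided by `c`
(for the low-survival exponential case `bX*tau_restrict/tau_max ≈ -0.0738`,
which is what the truth oracle indeed finds as the marginal hazard
difference). The rescaling is applied to simulated times only; the stored
coefficient set is never mutated, so provenance stays readable.

**Design choice (open in the sources we reconstruct):** the exact matching
procedure behind the published scale table is not available; fixing
`tau_restrict` by *reference-group* survival and rescaling is this
package's reconstruction, exposed as a pluggable `calibration` argument of
`lookup_coefficients()` so an alternative (e.g. matching
population-marginal survival) can be swapped in. Validation: the
reconstruction reproduces the published low-survival truths to ~0.002 on
the hazard-ratio scale and ~0.0015 on the hazard-difference scale (the
acceptance tests check this at 3 Monte-Carlo standard errors). Matching is
on 5-year survival only; the additive and multiplicative survival *curves*
differ before 5 years by construction, and no attempt is made to match
them.

A second reconstruction note: the printed survival-function table in the
source we follow writes `S(t) = S0(t)exp(W'beta)` for both DGM forms; the
additive exponent must carry `-t` and the multiplicative relation is
`S0(t)^{exp(W'beta)}`. The package implements the standard definitions
implied by the hazard functions, which are unambiguous.

## 3. Event-time generation

Multiplicative times invert the cumulative hazard in closed form. Additive
times solve `lambda*t^gamma + (W'beta)*t = -log(U)`; for `gamma != 1` a
*vectorised* bisection runs on the whole cohort simultaneously (100
halvings, absolute tolerance 1e-12, verified against a scalar bisection
oracle in the tests). Additive subjects whose cumulative hazard never
reaches `-log(U)` within the restricted horizon are carried as `Inf` and
end up administratively censored — they survive the follow-up window, and
no extrapolation beyond the horizon is ever needed.

The additive model does not force a positive hazard. The package checks
hazard positivity over the solution interval for every simulated subject
and **raises an error** (with counts and the offending linear-predictor
range) rather than truncating silently; in the grid scenarios the
violation probability per subject is below 1e-7, so desk-scale runs never
hit it, which is itself part of the stated world. An event exactly at the
censoring horizon counts as an event.

Reproducibility: one master seed expands to per-replicate substreams via a
counter-based integer hash (`substream_seed`), so any single replicate of
any scenario can be regenerated in isolation and results do not depend on
execution order or worker count.

## 4. The six analysis methods

All additive fits share one estimating-equation engine (C++): the
semiparametric model `h(t) = rho(t)'V + theta'W` where `V`-columns get
unrestricted time-varying coefficients and `W`-columns constant ones.
With `V = 1` this is the Lin–Ying constant-effects model; the naive fit
(AN) uses `W = (X, CM)`, the two-stage fit (A2S) uses `W = (Xhat, CM)`.
The control-function fit (ARI) uses `W = (X, CM)` and
`V = (1, Dhat, Z*Dhat)` with `Dhat = X - P(X=1|Z,CM)` from the shared
logistic first stage — exactly the model in which the treatment
coefficient is the marginal causal hazard difference for a binary
treatment, when hazards really are additive. The time-varying block is
profiled out by least squares on each risk set; integrals are discretised
over the distinct observed times with left-continuous risk sets, tied
events share a risk set, and the cumulative paths `R0(t)`, `R1(t)` are
returned as raw cumulative increments (no smoothing; how the reference
implementation smoothed them, if at all, is unknown). Variance is the
model-based sandwich with counting-process increments as the meat; a
nonparametric pairs bootstrap that re-runs both stages is available for
the structural Cox fit and could be added for the additive IV fits, and
the choice is recorded in every run log.

Cox fits (CN, C2S) wrap `survival::coxph` with **Breslow** tie handling
throughout — needed so the partial likelihood and the Breslow baseline
hazard are mutually consistent. C2S replaces `X` by the first-stage
prediction; its coefficient is not a causal quantity for binary `X` and
the fit object carries that caveat.

The structural Cox g-estimator (CSt) targets the hazard ratio of
treatment in the treated (ETT): with `g(Z) = Z - mean(Z)` and nuisance
survival `S_i = P(T_i > t | X_i, Z_i)` from a Cox model on `(X, Z)`
(options: add `CM`, add an `X:Z` interaction — the reference
specification is not stated; unadjusted is the default), `psi =
exp(-theta)` solves

```
sum_{X=0} g_i S_i  +  sum_{X=1} g_i S_i^psi  =  0.
```

The exponent form matters. The flattened source text reads as the product
`S_i * exp(-theta X_i)`, whose closed-form solution
`theta = -log(-A/B)` is retained as `solve_structural_cox()` (it is the
correct solution of the linearised equation, and the package's acceptance
fixture for it is hand-computable), but the estimator itself solves the
power form: only `S^{exp(-theta)}` is the counterfactual untreated
survival implied by a structural Cox model. Empirically the power form is
consistent (relative bias −0.04% at n = 100,000 under an additive DGM)
while the product form's `exp(theta)` converges to roughly the *inverse*
hazard ratio. The equation can genuinely lack a root (no sign change of
the estimating function over `psi` in `[1e-8, 1e8]`); this is reported as
`no_solution` and counted by the harness, never patched. Solving at
different evaluation times `t` can give different estimates; `t_eval`
defaults to the analysis horizon and per-year refits surface the curve
rather than averaging it.

Standardised survival predictions average subject-level predictions with
the treatment column forced to each arm: `exp(-H0(t) - theta'W*t - V'R(t))`
for additive fits, `exp(-H0(t)*exp(theta'W))` with the Breslow baseline
for Cox fits. Additive predictions can leave [0, 1]; they are **counted
and reported, never clipped**, mirroring the known pathology of additive
hazard models (negative hazard increments are similarly counted on every
fit). The structural Cox fit has no survival-prediction machinery — its
nuisance model is not a marginal outcome model — so the harness records
predictions for the other five methods.

## 5. The truth oracle

True causal contrasts are Monte-Carlo functionals of an *ideal RCT*
simulated under the same DGM: treatment randomised independently of
covariates with probability one half, full compliance, no censoring
before the analysis year. For each follow-up year the cohort is censored
at the year end and re-analysed: an unadjusted Cox fit gives the marginal
hazard ratio (a fast aggregated Newton solver for the single-binary-
covariate case, tested equal to `coxph` to 1e-8), an unadjusted Lin–Ying
fit the marginal hazard difference, per-arm Kaplan–Meier the true
survival, and `CM`-adjusted refits the conditional contrasts. The default
cohort size is 2,000,000; the acceptance runs use 500,000 (a warning marks
anything below 1,000,000) and every truth value carries the fitted model's
standard error as its MC uncertainty, so tolerance bands of 3 MC SEs are
always available.

The ETT needs one extra construction (its published derivation lives in
an unavailable supplement; this is the package's documented
reconstruction, cross-checked in the tests against an independent
probability-weighting oracle): simulate the *observational* treatment
assignment, and for the treated subgroup generate both potential event
times from the outcome model with shared covariates and a **shared
uniform draw**, then fit an unadjusted Cox model to the stacked
counterfactual pairs. The shared draw makes the construction
rank-preserving inside the simulator (for a protective effect every
`T1 > T0`), which is used as a sanity check only — the estimand does not
depend on the coupling.

Hazard differences are collapsible — the additive DGM's marginal and
conditional hazard differences agree — while hazard ratios are not: with
`bCM != 0` the conditional hazard ratio is farther from 1 than the
marginal one. Both facts are property-tested rather than assumed.

## 6. The replication harness and metrics

`run_scenario()` simulates replicated observational cohorts (defaults in
the full design: 1000 replicates at n = 2000 and 10,000; 200 at
n = 100,000), fits any subset of the six methods at each requested
analysis year, and records per-replicate estimates on each method's
native scale (hazard difference per year, or log hazard ratio), Wald 95%
confidence limits from sandwich standard errors, survival predictions
from the full-horizon fits, and every failure flag. Failed or
no-solution replicates are excluded from summaries *with their count
reported*.

`compute_metrics()` compares additive methods to the hazard-difference
truth and Cox methods to the hazard-ratio truth of the chosen target
(marginal, conditional, or ETT). Cox estimates and their confidence
limits are transformed to the HR scale for bias, relative bias and MSE
(matching how the headline relative-bias figures are quoted); power is
evaluated on the estimation scale against a null of zero. MSE is computed
as population variance plus squared bias and the identity is tested to
1e-12. The structural Cox bootstrap (200 percentile resamples by default
on a standalone fit) is disabled inside the harness by default
(`cst_nboot = 0`) because it multiplies the cost of every replicate by
the resample count; the run log records this, and coverage for CSt is
only reported when the bootstrap is on.

## 7. What the synthetic world does and does not establish

The generator emulates: unmeasured confounding of realistic strength,
instruments from very weak to strong, matched 5-year survival across
hazard scales, increasing/decreasing baseline hazards, and administrative
censoring. It deliberately does **not** emulate: random or informative
censoring, covariate-treatment interactions, time-varying treatment
effects, effect modification by `Z` beyond what non-collapsibility
induces, non-normal confounders, or misspecification of the first stage
other than the built-in probit-vs-logistic mismatch. A green test
therefore says: *the estimators and the oracle agree under the stated
world at the stated tolerances* — it does not certify behaviour under
informative censoring or in any real cohort.

Desk-scale choices, recorded so they are not mistaken for the full
design: acceptance tests run 200 replicates (not 1000) and truth cohorts
of 5e5 (not 2e6), with tolerances of 3 MC standard errors of the
scaled-down quantities; the structural-Cox mean over 200 replicates of a
heavy-right-tailed ratio estimator moves by a few MC SEs across seeds,
which is why its headline relative-bias check carries an explicit MC
tolerance term rather than a bare threshold.

## 8. Known limitations

* The additive-vs-multiplicative matching reconstruction reproduces
  printed low-survival truths closely but the high-survival matching
  constants of the original procedure are unknown; the hazard-difference
  truth for the low-survival additive exponential scenario sits ~0.0015
  from the printed value, near the edge of a 3-MC-SE band at 5e5.
* First-stage uncertainty is not propagated into the sandwich standard
  errors of the two-stage estimators (the pairs bootstrap is provided for
  CSt; extending it to A2S/ARI is mechanical but costly).
* The partly-parametric additive engine inverts a q×q risk-set Gram
  matrix at every distinct time; with purely administrative censoring the
  risk sets stay large and the matrix well-conditioned, but under heavy
  random censoring (out of scope) late risk sets could degenerate — the
  engine errors with the offending time rather than regularising.
* Survival predictions are reported at whole years from full-horizon
  fits; per-year refits change hazard contrasts, not the prediction
  mechanics.
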