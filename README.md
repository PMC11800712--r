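# hazivsim

A simulation laboratory for comparing **additive-hazards** and **Cox
instrumental-variable (IV) estimators** of causal treatment effects on
time-to-event outcomes when some confounders are unmeasured.

## The problem

Observational survival data with a binary treatment `X` are confounded by a
measured covariate `CM` and an unmeasured covariate `CU`.  A valid binary
instrument `Z` (associated with treatment, independent of `CU`, affecting
the outcome only through `X`) makes causal hazard contrasts identifiable.
How well the available estimators do in finite samples — and what happens
when an estimator's assumed hazard scale does not match the scale on which
nature is actually additive or multiplicative — is an empirical question
that this package answers by simulation.

Cohorts are generated as

```
Z ~ Bernoulli(0.5),   CM, CU ~ N(0, 1)
P(X = 1 | Z, CM, CU) = Φ(α₀ + α_Z Z + α_CM CM + α_CU CU)      (probit)
h(t) = h₀(t) + W'β            (additive DGM)
h(t) = h₀(t) · exp(W'β)       (multiplicative DGM)
W'β  = β₀ + β_X X + β_CM CM + β_CU CU
```

with exponential (`h₀(t) = λ`) or Weibull (`h₀(t) = λγt^{γ−1}`, γ ∈
{0.5, 1.5}) baselines, administrative censoring at 5 years, and the scale
`λ` calibrated so the reference group has 5-year survival 0.60 ("high") or
0.30 ("low").  Additive and multiplicative scenarios are matched on 5-year
survival: additive event times are simulated on a restricted horizon and
rescaled (`λ_A = 0.1 λ_M`, `c = τ_max/τ_restrict`).  The full grid crosses
3 baselines × 2 survival levels × 3 effect sizes × 4 instrument strengths ×
3 confounding strengths × 2 DGM forms = **432 scenarios**.

Six analysis methods are implemented:

| Code | Method                              | Estimand (if causal)     |
|------|-------------------------------------|--------------------------|
| AN   | naive additive hazards (Lin–Ying)   | marginal hazard difference |
| CN   | naive Cox                           | conditional hazard ratio |
| A2S  | two-stage additive IV               | marginal hazard difference |
| ARI  | two-stage residual inclusion (control function) additive IV | marginal hazard difference |
| C2S  | two-stage Cox IV                    | (not causal for binary X) |
| CSt  | structural Cox g-estimator          | hazard ratio of treatment in the treated (ETT) |

The two-stage methods share a first-stage *logistic* regression of `X` on
`(Z, CM)` — deliberately mismatched with the probit data-generating model.
ARI fits `h(t) = h₀(t) + θ_X X + θ_CM CM + (ρ₀(t) + ρ₁(t)Z)Δ̂` with
unrestricted time-varying coefficients on the first-stage residual `Δ̂`.
CSt solves the g-estimating equation
`Σᵢ {g(Zᵢ) − ḡ} Ŝᵢ^{exp(−θXᵢ)} = 0` with `g(Z) = Z − mean(Z)` and nuisance
survival `Ŝᵢ = P(Tᵢ > t | Xᵢ, Zᵢ)` from a Cox model.

True causal contrasts (marginal and conditional hazard ratios and
differences, the ETT hazard ratio, and per-arm survival) are obtained from
a Monte-Carlo oracle: a huge simulated RCT analysed with unadjusted Cox and
additive fits and Kaplan–Meier curves, censored at each follow-up year.
A replication harness computes bias, relative bias, MSE, coverage, power
and survival-prediction error summaries against those truths.

## Worked example

```r
library(hazivsim)

spec <- scenario_spec(dgm_form = "additive", baseline = "exponential",
                      survival_level = "low", effect_size = "large",
                      iv_strength = "moderate", confounding = "strong")
lookup_coefficients(spec)
#> <haziv_coefs> additive DGM, shape 1.0, scale 0.02408
#>   alpha: a0=0 aZ=0.5 aCM=-0.2 aCU=-0.5
#>   beta:  b0=0.4 bX=-0.13 bCM=0.02 bCU=0.05
#>   follow-up restricted to 2.839 y, times rescaled by 1.761

cohort <- simulate_observational_cohort(spec, n = 10000, seed = 2024)
first  <- fit_treatment_model(cohort)
round(unlist(iv_strength_summary(cohort)), 3)
#>    p1    p0  diff
#> 0.673 0.505 0.168        # a "moderate" instrument: ~17 percentage points

fit_additive_naive(cohort)
#> <haziv_addfit> n = 10000, events = 6115
#>            coef          se
#> X  -0.097847426 0.005519550
#> CM  0.006665966 0.002492797

fit_additive_2sri(cohort, first)
#> <haziv_addfit> n = 10000, events = 6115
#>            coef          se
#> X  -0.071238516 0.029742237
#> CM  0.008258106 0.003007192
#>   time-varying terms: baseline, Dhat, ZxDhat

fit_structural_cox(cohort, nboot = 0)
#> <haziv_structural_coxfit> t_eval = 5
#>   ETT log HR = -0.2993 (HR 0.7413), bootstrap se = not run

truth <- true_marginal_contrasts(spec, n_mc = 5e5, seed = 1, years = 5)
round(as.data.frame(truth), 4)
#>   year hr_marginal hr_marginal_se hd_marginal hd_marginal_se     S1     S0
#> 1    5      0.6921         0.0025     -0.0734          7e-04 0.4389 0.3045
```

Reading the output: the true marginal hazard difference in this scenario
is −0.073 events per person-year.  The naive additive fit, which cannot
see `CU`, reports −0.098 — a ~33% exaggeration of the protective effect,
with a deceptively small standard error.  The control-function IV fit
(ARI) recovers −0.071, within one (much larger, honest) standard error of
the truth.  The structural Cox fit estimates the hazard ratio of treatment
in the treated.

Replicated runs and the full metric table:

```r
res <- run_scenario(spec, methods = c("AN", "ARI", "CSt"), n_reps = 100,
                    n = 10000, seed = 7)
met <- compute_metrics(res, truth)          # bias, MSE, coverage, power
err <- survival_prediction_error(res, truth)
report(res, met, "out/")                    # delimited-text artefacts
```

A minimal command-line interface mirrors the library:

```sh
Rscript -e 'hazivsim::haziv_cli()' calibrate --out manifest.csv
Rscript -e 'hazivsim::haziv_cli()' simulate --scenario 5 --n 10000 --seed 3 --out cohort.csv
Rscript -e 'hazivsim::haziv_cli()' truth --scenario 5 --n-mc 500000 --out truth.csv
Rscript -e 'hazivsim::haziv_cli()' run --scenario 5 --reps 100 --out results/
```

## Documentation

The methods vignette (`vignettes/iv-survival-simulation.Rmd`) describes
the data-generating mechanisms, the calibration strategy, each estimator's
assumptions, the Monte-Carlo truth oracle, the numerical choices, and what
the synthetic-data tests do and do not establish.
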