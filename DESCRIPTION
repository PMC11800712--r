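Package: hazivsim
Title: Simulation Laboratory for Instrumental-Variable Survival Estimators
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A simulation laboratory comparing additive-hazards and Cox
    instrumental-variable (IV) estimators for time-to-event outcomes under
    unmeasured confounding.  Provides matched additive and multiplicative
    data-generating mechanisms with exponential and Weibull baseline
    hazards, probit treatment assignment with a binary instrument, six
    analysis methods (naive additive and Cox models, two-stage and
    two-stage-residual-inclusion additive IV models, two-stage Cox IV, and
    the structural Cox g-estimator of the effect of treatment in the
    treated), a Monte-Carlo oracle for the true marginal, conditional and
    treated-subgroup causal hazard contrasts, and a replication harness
    computing bias, relative bias, mean squared error, coverage, power and
    survival-prediction error summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
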