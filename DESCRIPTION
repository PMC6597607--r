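Package: pedpk
Title: Pediatric Population Pharmacokinetics and Between-Drug Clearance Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical nonlinear mixed-effects modelling of pediatric
    pharmacokinetic studies with allometric covariate functions, and
    between-drug extrapolation of CYP3A-mediated clearance from adults to
    children. Provides analytical one- and two-compartment oral models,
    a Laplace (FOCE with interaction) marginal-likelihood estimator with
    empirical Bayes estimates, conditional weighted residuals, stepwise
    covariate selection, nonparametric bootstrap and normalized prediction
    distribution errors (NPDE), simulators for dense single-dose and sparse
    steady-state study designs, and weight-based clearance scaling with
    prediction-error accuracy classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
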