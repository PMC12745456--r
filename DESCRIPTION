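Package: rixfp
Title: Population Pharmacokinetics and Dosing-Regimen Simulation for
    Albumin-Fused Factor IX
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population pharmacokinetics of rIX-FP, a
    recombinant factor IX-albumin fusion protein used for prophylaxis in
    hemophilia B. Implements the closed-form two-compartment infusion
    model with allometric body-weight and weight-adjusted-dose covariate
    laws, decomposition of observed factor IX activity into exogenous
    drug, endogenous baseline and decaying prior-product components,
    age-stratified virtual-cohort generation calibrated to per-kilogram
    clearance medians, Monte-Carlo dosing-regimen simulation (durations
    above activity thresholds, steady-state troughs, target-attainment
    percentages, exposure metrics), a Laplace-approximation nonlinear
    mixed-effects estimator with likelihood-ratio covariate testing, and
    prediction-corrected visual predictive checks. Datasets use
    NONMEM-compatible long-format tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
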