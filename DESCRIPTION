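Package: neovanc
Title: Population Pharmacokinetics and Model-Based Dosing of Intravenous
    Vancomycin in Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment infusion population-pharmacokinetic model of
    intravenous vancomycin in neonatal intensive care patients, with
    allometric weight scaling, Hill-type postmenstrual-age maturation and a
    serum-creatinine power term on clearance. Provides event-record
    preprocessing with LLOQ and censoring rules, Laplace (FOCE-I type)
    population fitting with the M3 method for below-quantification data,
    MAP Bayesian individual estimation, AUC24/MIC probability-of-target-
    attainment dose optimization (empirical, Bayesian, trough-based and
    weight-based comparators), prediction-corrected visual predictive
    checks, a calibrated synthetic-cohort simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
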