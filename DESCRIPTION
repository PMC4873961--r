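Package: cmodel
Title: Case-Mix Adjusted Benchmarking of Caesarean Section Rates
Version: 1.0.0
Authors@R:
    person("C-Model", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking caesarean section (CS) rates at health
    facilities against a case-mix adjusted expected rate. Implements the
    Robson ten-group classification, four published logistic scoring models
    for the individual probability of caesarean section, observed-versus-
    expected benchmarking with standardised CS ratios and uncertainty
    ranges, and the validation machinery used to assess such models:
    ROC curves with Hanley-McNeil standard errors, ROC-derived cut-offs,
    classification tables and diagnostic odds ratios, quintile calibration,
    and DerSimonian-Laird random-effects meta-analysis of AUCs. Includes a
    reference-population builder (facility indicators, double-median
    stratification, random 90/10 split, from-scratch logistic fitting) and
    a synthetic multi-facility obstetric data generator so every component
    is testable without access to confidential delivery records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
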