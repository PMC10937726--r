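Package: pdprogression
Title: Comparing Parkinson's Disease Progression in Research and Real-World Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare Parkinson's disease progression between
    research-style cohorts and real-world (EHR/claims) populations. Provides a
    calibrated synthetic longitudinal EHR/claims generator, incident-cohort
    phenotyping with a pre-diagnosis quiescence rule, clinical rating score
    extraction from notes under a self-consistency voting protocol with
    stratified audit sampling, clinical event detection (therapy-initiation
    episodes, cognitive decline, Hoehn & Yahr threshold crossing, adverse
    events), and survival and progression statistics (Kaplan-Meier, log-rank,
    test routing, covariate-adjusted progression regression, missingness
    audit).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    car,
    pROC,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
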