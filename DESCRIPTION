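Package: akialert
Title: KDIGO Creatinine-Based AKI Detection, Electronic Alerting, and
    Randomized-Trial Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and stages acute kidney injury (AKI) from longitudinal
    inpatient serum-creatinine series using the KDIGO creatinine criteria,
    computes CKD-EPI estimated glomerular filtration rate, screens episodes
    against the eligibility rules of a pragmatic electronic-alert trial,
    performs stratified seeded 1:1 randomization with throttled alert
    messages, derives the trial's primary, secondary and care-centered
    outcomes over their time windows, and provides the trial's statistical
    machinery (Wald risk differences, chi-square, Mann-Whitney,
    Hodges-Lehmann shift estimates, univariate logistic subgroup analysis
    with interaction, and power-based sample size). A synthetic
    electronic-health-record generator produces cohorts with configurable
    AKI incidence, stage mix and per-arm care-process effects so the whole
    pipeline runs end-to-end without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
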