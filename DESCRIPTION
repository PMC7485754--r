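Package: trdclaims
Title: Claims-Based Phenotyping and Economic Burden Analysis of
    Treatment-Resistant Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying treatment-resistant depression (TRD) in
    administrative claims data: a synthetic claims generator with known
    ground truth, cohort construction under incident-user inclusion and
    exclusion rules, a line-of-therapy TRD phenotyping algorithm based on
    regimen failure rules (switch and augmentation pathways with adequate
    dose and duration), Elixhauser comorbidity scoring, propensity-score
    greedy caliper matching, and adjusted healthcare utilization and cost
    models (negative-binomial and gamma log-link GLMs with percentile
    bootstrap confidence intervals, and a repeated-measures logistic model
    with exchangeable working correlation and robust variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
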