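Package: radstrat
Title: Frequency-Ranked Radiomic Biomarkers for Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies prognostic radiomic biomarkers from right-censored
    survival cohorts by repeated elastic-net-penalized Cox regression over a
    grid of mixing parameters, ranking features by how often they receive a
    non-zero coefficient across Monte Carlo resamples. Redundancy among
    top-ranked features is quantified by mean absolute Spearman correlation
    (a representativeness strength score) to pick a single representative
    biomarker, which then drives hierarchical risk stratification:
    median dichotomization, nested subgroup construction, Kaplan-Meier
    estimation with Greenwood confidence bands, two-group log-rank tests,
    and exploratory SMOTE-style rebalancing of small survival subgroups.
    Includes a synthetic radiomic-survival cohort generator with planted
    hazard effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
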