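Package: skelage
Title: Non-Invasive Skeletal Age Estimation and Maturity Classification
    for Youth Soccer Players
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates skeletal age (SA) in male youth soccer players from
    the percentage of adult height (PAH), a non-invasive somatic maturity
    indicator. Provides Khamis-Roche style adult-height prediction from a
    swappable coefficient table, PAH computation, age-specific PAH cut-off
    classification into late, on-time and early maturers, general and
    maturity-stage-specific SA prediction equations, the full model
    development machinery (closed-form ordinary least squares with
    Durbin-Watson, Kolmogorov-Smirnov and homoscedasticity diagnostics),
    ROC-based cut-off derivation via the Youden index with DeLong
    confidence intervals, an agreement suite (Bland-Altman, intraclass
    correlation, Cohen's kappa, Kendall's tau-b, percent agreement,
    repeated-measures ANOVA), a seeded synthetic growth-cohort simulator,
    and a command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    lmtest,
    withr,
    jsonlite
Config/testthat/edition: 3
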