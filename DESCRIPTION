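Package: t2dcea
Title: Lifetime Microsimulation and Trial-Based Cost-Utility Analysis for
    Type 2 Diabetes Weight-Management Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Health-economic evaluation toolkit for structured diabetes
    education with and without behavioural weight management in people with
    recently diagnosed type 2 diabetes. Provides a synthetic-cohort
    generator with correlated metabolic risk factors, trial design
    calculations (ANCOVA-style sample size, categorical outcome summaries,
    pattern-mixture delta adjustment), intervention costing scenarios, a
    within-trial cost-utility analysis with nonparametric bootstrap and
    cost-effectiveness acceptability curves, and a lifetime patient-level
    microsimulation with configurable parametric risk equations, hazard
    calibration, diabetes-remission medication cost offsets, discounted
    QALY and cost accrual, probabilistic sensitivity analysis and subgroup
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
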