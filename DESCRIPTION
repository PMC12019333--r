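Package: pcclock
Title: Clinical Biological-Age Clocks from Principal Components and Cox
    Regression
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains, scores, benchmarks and interprets clinical
    biological-age clocks built from routinely collected laboratory and
    examination parameters. Clinical parameters are robustly normalized
    (log transforms, median/MAD z-scores against a young reference
    cohort, six-SD outlier capping), reduced to sex-specific principal
    components by singular value decomposition, and weighted by a Cox
    proportional-hazards model; the linear predictor is mapped to a
    biological age in years through the Gompertz mortality-rate
    doubling time estimated from a chronological-age-only null model.
    Includes k-year mortality ROC benchmarking with DeLong comparisons
    against theoretical reference clocks (CrystalAge, RandomAge),
    Kaplan-Meier quartile stratification with
    Benjamini-Hochberg-corrected log-rank tests, PC-outcome association
    heatmaps, per-subject principal-component contribution reports,
    healthspan markers, and a synthetic Gompertz-cohort generator so
    every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
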