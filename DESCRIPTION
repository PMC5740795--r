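Package: traumascore
Title: Trauma Mortality Scores and Discrimination Analysis on Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the standard trauma mortality prediction scores
    (ISS, NISS, RTS, and the MTOS- and NTrD-coefficient TRISS survival
    probabilities) from patient-level registry records, and evaluates their
    discrimination for in-hospital death: empirical ROC curves, AUC with
    DeLong standard errors and confidence intervals, paired DeLong tests
    between correlated AUCs, and Youden-index optimal cutoffs with the full
    confusion-matrix panel (sensitivity, specificity, accuracy, PPV, NPV).
    Includes delimited-text registry input/output with validation rules, a
    calibrated synthetic trauma cohort generator for running the full
    analysis without access to a hospital registry, and an end-to-end
    pipeline that renders the summary, AUC, pairwise-comparison and cutoff
    tables plus an ROC overlay figure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
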