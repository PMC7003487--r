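Package: glyconact
Title: Serum IgG N-Glycomics Analysis for Predicting Neoadjuvant
    Chemotherapy Response in Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serum IgG N-glycome profiling in locally
    advanced gastric cancer treated with neoadjuvant chemotherapy (NACT).
    Parses glycan compositions (Hex/HexNAc/Fuc/NeuAc), owns a 24-peak
    HILIC-UPLC reference panel, performs total-area normalization of peak
    areas (with optional fixed-window trapezoidal integration of raw
    chromatogram traces), computes 17 summarized glycan traits including the
    Gal-ratio, runs two-group univariate screening (t-tests, chi-squared or
    Fisher tests, per-feature ROC AUC with DeLong confidence intervals),
    fits the clinical, glyco and combined logistic prediction models with
    optional stepwise selection, and simulates two-group compositional
    cohorts (logistic-normal on the percent simplex) calibrated to the
    published group-mean profiles so that every stage is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    pROC,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
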