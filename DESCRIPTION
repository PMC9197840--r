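Package: metrisk
Title: Metastasis-Risk Analysis of Annotated Tumor Whole Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating metastasis risk of primary
    cutaneous squamous cell carcinoma from annotated whole slide images:
    synthetic annotated slide and cohort generation, tile extraction with
    tissue (Otsu) and tumor-annotation validity rules, patient-exclusive
    cross-validated tile classification with out-of-fold probabilities,
    tile-to-slide score aggregation with spatial median smoothing and
    probability heatmaps, contingency-table odds ratios and ordinal
    concordance AUROCs for risk-factor models, and Kaplan-Meier survival
    summaries. Bundles the published contingency counts so the downstream
    statistics are exactly reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
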