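Package: ersrisk
Title: CSF Biomarker Risk Scoring and Dementia-Risk Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Erlangen Score, an ordinal 0-4 cerebrospinal-fluid
    biomarker risk score for Alzheimer's disease built from Abeta1-42,
    pTau181, total tau and the Abeta1-42/Abeta1-40 ratio, and compares it
    against the pTau/Abeta1-42 ratio as a predictor of cognitive decline and
    conversion to dementia. Provides three-zone marker classification around
    assay cut-offs, Youden-index cut-off calibration, linear mixed models of
    longitudinal MMSE z-scores with AR(1) residual correlation fitted by
    maximum likelihood, Cox proportional-hazards conversion probabilities
    with time-dependent ROC analysis and paired DeLong AUC comparison,
    diagnostic 2x2 summaries, and a synthetic memory-clinic cohort generator
    so the full pipeline is testable without patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    nlme,
    pROC,
    withr,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
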