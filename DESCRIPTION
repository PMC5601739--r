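Package: pepdiag
Title: Serum Peptidome Diagnostic Panels from MALDI-TOF Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating peptide diagnostic panels from
    MALDI-TOF serum peptidome profiles. Covers simulation of labelled two-cohort
    spectral datasets, spectral preprocessing (moving-average smoothing, baseline
    estimation and subtraction, local noise estimation, signal-to-noise peak
    detection, total-ion-current normalization), cross-sample peak alignment into
    a reference peak matrix with a presence filter, Shapiro-Wilk-gated univariate
    candidate selection with per-peak ROC/AUC, stepwise multivariate binary
    logistic panel construction, and frozen-coefficient external validation with
    full diagnostic-performance reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
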