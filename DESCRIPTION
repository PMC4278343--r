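Package: methpanel
Title: Multi-Marker DNA Methylation Panel Diagnostics for Prostate Biopsy Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-marker methylation-specific qPCR
    (MS-qPCR) panels applied to prostate biopsy cores. Converts cycle-threshold
    (Cq) values to binary methylation calls and semi-quantitative levels, pools
    dual assays per marker, and computes per-marker and k-of-N composite
    operating characteristics with Wald confidence intervals, ROC/AUC analyses
    based on methylated-marker counts and levels, within-case paired
    comparisons, age associations, and cross-validated best-subsets logistic
    model ranking with frozen-coefficient out-of-sample evaluation. Includes a
    synthetic case/control cohort generator calibrated to published per-marker
    methylation frequencies so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
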