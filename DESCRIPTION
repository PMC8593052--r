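Package: framingbench
Title: Temporal Framing Structures for Clinical Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for studying how the temporal framing of a machine-learning
    risk prediction problem shapes model performance on longitudinal inpatient
    records. Provides a tabular cohort data model with readers, writers and a
    length-of-stay inclusion filter; a Sepsis-3 onset labeler (suspected
    infection from culture/antibiotic event pairs plus an acute two-point SOFA
    increase); four framing structures that convert labeled admissions into
    supervised prediction samples (fixed time to onset, sliding window,
    sliding window with dynamic inclusion, on clinical demand); a feature
    pipeline that turns 12-hour observation windows over a 25-parameter
    schema into 50-element feature vectors; a grouped five-fold evaluation
    bench with AUROC, AUPRC, stratified Brier scores and average calibration
    error; and a synthetic electronic-health-record generator with planted
    sepsis episodes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    ranger,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
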