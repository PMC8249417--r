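Package: drgcast
Title: Early Prediction of Diagnosis-Related Groups and Case-Mix Index from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-stay diagnosis-related groups (DRGs) from timestamped
    clinical notes with a convolutional neural network pooled by per-label
    attention, maps predictions to DRG relative weights, and estimates
    population case-mix index (CMI) and prospective-payment cost as a function
    of time since ICU admission and cohort size. Includes a synthetic-data
    generator that emulates MIMIC-like note tables with planted, time-accruing
    diagnostic n-gram signal, cohort-construction filters with patient-level
    train/test and cross-validation splitting, tokenization and fixed-length
    encoding, macro/micro AUC and F1 evaluation over DRG subsets, and
    bootstrap analyses of CMI error across admission-time cutoffs and
    population sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
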