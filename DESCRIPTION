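Package: syncopenb
Title: Literature-Based Naive Bayes Classification of Cardiac Syncope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools published predictor-by-diagnosis frequency tables for
    syncope into conditional probability tables and combines them with
    population-specific prior prevalences in a naive Bayes (joint
    Bernoulli) model of cardiac syncope. Provides predictor selection and
    association statistics for the pooled tables, posterior prediction for
    patient cohorts with missing values, ROC/c-statistic evaluation at a
    sensitivity-favouring cutoff, stratified resampling to standardize
    cohorts to a reference age-by-spells distribution, and a synthetic
    multi-centre cohort generator so the whole pipeline can be exercised
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
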