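Package: proscore
Title: Derivation and Evaluation of Point-Based Prehospital ROSC Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving, aggregating and evaluating point-based
    clinical risk scores for prehospital return of spontaneous circulation
    (ROSC) after out-of-hospital cardiac arrest. Implements the full
    derivation pipeline: random-forest variable ranking with a parsimony
    curve, quantile categorisation of continuous predictors, conversion of
    logistic-regression coefficients to integer points, per-community score
    derivation with AUC- and size-weighted aggregation, and normalisation to
    a maximum of 100 points. Ships the published P-ROSC score table, a
    score-to-probability conversion table builder, generic logit-formula and
    additive-table comparator scorers with registry recoding rules, ROC/AUC
    evaluation with DeLong tests, and a synthetic multi-community
    cardiac-arrest registry simulator for testing every stage without access
    to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
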