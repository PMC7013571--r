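Package: myoscreen
Title: Longitudinal Myopia Risk Screening, Imputation and Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal school-cohort refraction data:
    simulation of student-by-grade cohorts with planted risk-factor effects and
    grade-biased missingness, two-stage (univariate then multivariate)
    correlation screening of candidate factors, imputation of missing diopter
    records with gradient-boosted regression trees selected by the REP
    statistic (fitting goodness divided by absolute error rate),
    factor-type-specific longitudinal feature transforms, and a linear
    support-vector-machine myopia predictor with a full evaluation harness
    (confusion metrics, ROC/AUC, stratified cross-validation, baseline
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    e1071,
    class,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr
biocViews: Epidemiology, Regression, Classification, MissingData
Config/testthat/edition: 3
RoxygenNote: 7.3.3
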