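Package: consig
Title: Consensus Gene Expression Signatures of Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extraction and evaluation of consensus gene expression
    signatures of chemotherapeutic response from cell line panels.
    Seed genes are found per data fold as the intersection of three
    differential-expression tests between extreme responders (an
    empirical-Bayes moderated t-test, a permutation-based SAM
    d-statistic, and a bootstrap single-step minP adjustment), then
    filtered by co-expression connectivity in a clinical cohort, and
    combined across folds into a consensus signature.  Includes
    signature scoring, quality-control metrics with a radar-area
    summary, cell line persistence curves (Kaplan-Meier estimates over
    IC50), random-signature null calibration, a suite of IC50
    prediction models, disease-site rank concordance, mutation
    association, and Cox proportional-hazards translation with optimal
    cutpoint search.  A synthetic-data generator with a planted
    sensitivity program supports end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    e1071,
    randomForest,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
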