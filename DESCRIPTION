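Package: svmop
Title: Ordinal Regression by Support Vector Machine Ordinal Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ordinal regression for graded outcomes (such as five-level
    patient-satisfaction ratings) by ordinal partitioning: a P-class ordered
    problem is decomposed into P-1 binary "is the rank greater than p?"
    sub-problems, each solved as a linear support vector machine by dual
    coordinate descent, and the sub-model scores are joined by a counting
    prediction rule. Includes a feature pipeline for consultation-style
    text records (dictionary-based customized features, TF-IDF unigram and
    bigram features, and gradient-boosted-tree leaf encodings), naive
    one-versus-rest and regression baselines, ordinal evaluation metrics
    (MAE, MSE, pairwise accuracy), weight-norm feature-importance mining,
    and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
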