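Package: twiner
Title: Twin-Network Correlation-Based Regularization for Sparse Logistic
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene signatures shared by two diseases from
    transcriptomic data. For each gene the angular distance between its
    correlation vectors in the two diseases is turned into an elastic-net
    penalty factor, so genes with similar ("twin") co-expression patterns
    across diseases are penalized less during sparse logistic regression.
    Includes a coordinate-descent solver for the weighted elastic-net
    penalty, a resampling protocol with consensus-signature extraction and
    selection-frequency stability analysis, correlation-network export for
    selected genes, survival-based risk stratification of signatures via
    Cox regression and the log-rank test, and a synthetic two-cohort data
    generator with planted twin, disease-specific and noise gene blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    survival
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
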