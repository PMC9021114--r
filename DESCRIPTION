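Package: ggmeta
Title: Maximum Likelihood and Meta-Analytic Estimation of Gaussian
    Graphical Models from Correlation Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum likelihood estimation of Gaussian graphical models
    (partial correlation networks) from one or several sample correlation
    matrices. Provides analytic matrix-calculus derivatives for the
    standardized Gaussian likelihood, Wald-based significance pruning,
    equality constraints across datasets, fixed-effects meta-analytic
    aggregation (two-stage weighted least squares or multi-dataset
    equality-constrained estimation), an exploratory partial-pruning
    search for cross-dataset differences, and random-effects
    meta-analytic aggregation in which cross-study heterogeneity of the
    correlational structure is modeled through a Cholesky-parameterized
    covariance component. Includes a simulation harness that generates
    small-world partial-correlation networks, injects correlated random
    effects, samples finite-sample correlation matrices, and scores
    network recovery (sensitivity, specificity, edge-weight correlation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
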