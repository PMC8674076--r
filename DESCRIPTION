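Package: orlrs
Title: One-Step Robust Low-Rank Subspace Segmentation for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Clusters the samples of a gene-expression matrix by one-step
    robust low-rank subspace segmentation: a single augmented Lagrange
    multiplier optimization that simultaneously learns a low-rank
    representation, a capped-norm regularized noise matrix, and discrete
    cluster indicators, returning cluster labels directly without a separate
    spectral-clustering step. Includes a noiseless one-step baseline solver,
    clustering accuracy and normalized mutual information metrics, a
    union-of-subspaces fixture generator, PCA/K-means preprocessing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
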