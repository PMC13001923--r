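Package: graphomix
Title: Similarity-Network Design for Graph-Based Multi-Omics Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks how the construction of patient similarity networks
    affects graph convolutional multi-omics classification. Implements six
    sample-graph constructions (cosine and RBF similarities and distances,
    plus their hybrid convex combinations) with top-k sparsification and
    symmetric normalization, per-view two-layer graph convolutional
    classifiers fused by a view-correlation tensor network, a synthetic
    multi-omics generator with directional class signal and multiplicative
    scale jitter, the standard expression preprocessing chain
    (log transform, variability filtering, KNN imputation, quantile
    normalization), and a repeated stratified-split benchmark harness with
    paired t-tests, confidence intervals and Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
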