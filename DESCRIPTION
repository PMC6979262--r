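Package: rdrbench
Title: Rediscovery-Rate Benchmarking of Single-Cell Differential Expression Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for two-group differential expression
    (DE) analysis of single-cell RNA-seq expression matrices. Provides a
    four-parameter beta-Poisson count simulator with configurable
    differential-expression injection, seven natively implemented DE tests
    spanning the main model families (Welch t, Wilcoxon rank-sum,
    trend-moderated t, negative-binomial Wald, zero-inflated
    negative-binomial likelihood ratio, two-part hurdle, and a beta-Poisson
    GLM z-test), and an evaluation engine measuring type-I error, top-k
    rediscovery rates between disjoint training and validation cell sets,
    and ROC/AUC, stratified by expression level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
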