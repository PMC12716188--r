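Package: tregsig
Title: Chicken Regulatory T Cell Signature Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementation of the computational analysis behind a
    chicken regulatory T cell (Treg) transcriptomic signature: single-cell RNA-seq
    quality control, normalization, graph-based clustering, FOXP3-positive cluster
    identification and a mean-expression-ratio marker score; a from-scratch
    negative-binomial GLM differential-expression engine (median-of-ratios
    normalization, moderated dispersion estimation, Wald and likelihood-ratio
    tests) for the CD25-sorted bulk populations; delta-delta-CT qPCR relative
    quantification with one-way ANOVA and Tukey HSD group comparisons; and a
    synthetic-data generator that emulates the statistical structure of all three
    assays with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    S4Vectors,
    mclust,
    withr
Config/testthat/edition: 3
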