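Package: tmestroma
Title: Stromal Cell Heterogeneity Analysis for Pan-Cancer Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for examining stromal cell heterogeneity in
    the tumor microenvironment from single-cell RNA sequencing data across
    cancer types. Provides unified quality control and normalization for
    UMI-based and full-length platforms, variance-stabilizing-transformation
    selection of highly variable genes, covariate regression, PCA and
    graph-based clustering with marker-based major-cell-type annotation,
    signature-centroid classification of endothelial and
    fibroblast/myofibroblast subtypes with permutation-based unknown
    rejection, composition tables stratified by cancer type, tissue and
    patient age, and from-scratch single-sample gene set enrichment (ssGSEA)
    scoring of pathway activity. Includes a negative-binomial synthetic data
    generator with planted cell types and subtypes so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
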