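Package: stratameta
Title: Depth-Stratified Metatranscriptome Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of depth-stratified marine community
    metatranscriptomes: consensus multi-tool classification of
    carbohydrate-active enzyme (CAZyme) open reading frames together with
    peptidase (MEROPS), membrane-transporter (TCDB) and archaeal marker-gene
    annotation; count normalization (cpm, TPM, Hellinger, scaling with ranked
    subsampling); richness and evenness estimation; transformation-based
    ordination (PCA, RDA with environmental-variable selection, permutation
    inference and variance partitioning), PERMANOVA and Ward clustering; and
    taxon-resolved gene-system investment log-ratio and marker-gene ratio
    statistics. Ships a stratified-community synthetic data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
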