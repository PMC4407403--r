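Package: cnarray
Title: Gene-Level Copy Number Alteration Arrays from Probe-Level aCGH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts probe-level array-CGH copy-number log2 ratios into
    gene-level copy number alteration (CNAR) matrices. Gene regions are
    extended by a promoter and flanking window into probe-capture
    "pseudogenes"; a sparse genes-by-probes base matrix (binary or
    probe-averaged weights) maps probe measurements to genes by a single
    matrix product. Includes variance filtering, Fisher-criterion feature
    ranking, leave-one-out cross-validated classification with nested
    feature selection, silhouette validation, resampling consensus
    clustering, a class-structured cohort simulator with known driver
    genes, and GCT/CLS/BED export so that expression-analysis toolchains
    can consume copy-number data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    cluster,
    e1071,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
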