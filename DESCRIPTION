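Package: scImmuRank
Title: Hierarchical Immune Cell Type Annotation for Single-Cell RNA-Seq by
    Per-Cell Gene Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates immune cell types in single-cell RNA-seq count
    matrices by computing single-sample gene set enrichment (ssGSEA) scores
    per cell against curated signature gene sets organized in a three-layer
    differentiation hierarchy (nine major immune types, 16 second-layer
    subtypes, 13 T-cell subtypes). Each cell is first screened as immune
    versus non-immune, then labelled layer by layer: subtypes compete only
    with siblings under the cell's parent label, and the set with the
    largest enrichment score wins. Includes marker-gene screening by average
    expression across reference datasets, an evaluation harness with label
    harmonization, stratified subsampling and confusion-matrix metrics, a
    negative-binomial synthetic-data generator with known hierarchical
    labels, and a command-line interface. Reads Matrix Market triplet and
    dense CSV/TSV matrices and GMT gene set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
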