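Package: methlineage
Title: Meta-Epigenomic Methylation Analysis and Data-Driven Lineage
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of low-input and single-cell whole-genome bisulfite
    sequencing data aggregated over regulatory regions: pooling of many
    small-pool replicate methylomes into meta-epigenomic consensus profiles,
    region- and region-set-level differential methylation statistics
    (Welch t and Wilcoxon rank-sum with dual FDR/effect-size thresholds),
    region-set overlap enrichment via Fisher's exact test, multinomial
    elastic-net cell-type classification with cross-validation and
    signature-region extraction, and reconstruction of a cell-type lineage
    graph from leave-one-class-out cross-prediction probabilities.
    Includes a synthetic-study generator emulating the pooled sampling
    design (eight 10-cell pools, two 50-cell pools and one 1,000-cell pool
    per donor and cell type, three donors) with a known lineage tree, for
    end-to-end validation against planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
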