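Package: ccalign
Title: Single-Cell Data Alignment with Non-Linear Probabilistic Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns multiple single-cell datasets (scRNA-seq counts and/or
    scATAC-seq gene-activity matrices) into a shared low-dimensional latent
    space using a conditional variational autoencoder that generalizes
    probabilistic canonical correlation analysis with a non-linear decoder
    and dataset-specific batch codes. Provides batch-free recovered
    expression, reference-based cell-type label transfer across modalities,
    and an integration-quality metric battery (kBET acceptance rate, mixing
    metric, Louvain clustering with adjusted Rand index, Wilcoxon rank-sum
    differential expression with Bonferroni control). Includes readers for
    MatrixMarket, dense TSV/CSV and 10x-style HDF5 matrices, CPM-log
    normalization, consensus highly-variable-gene selection, peak-to-gene
    activity conversion, a multi-batch synthetic count generator, and a
    command-line interface.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    RANN,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    rhdf5,
    tools
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), mclust, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
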