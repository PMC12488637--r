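Package: citeqc
Title: Quantitative Quality Control for CITE-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-layered quality control for CITE-seq experiments, which
    jointly assay the transcriptome and a panel of antibody-derived tags
    (ADTs) in single cells. Provides per-modality read-count diagnostics
    (nCount/nFeature and mitochondrial-fraction relationships) scored with
    Spearman correlation and permutation p-values, RNA-based graph
    clustering with one-vs-rest marker detection, cluster-conditional
    Shannon-entropy specificity scores for genes and ADTs, RNA-protein
    concordance analysis per pair and per cluster, controlled
    noise-injection experiments that verify metric sensitivity, an
    empirical entropy cutoff for marker specificity calibrated on
    non-differential genes, a negative-binomial synthetic data generator
    with known ground truth, and a one-call markdown QC report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    igraph,
    irlba,
    RANN
Suggests:
    testthat (>= 3.0.0),
    uwot,
    optparse
Config/testthat/edition: 3
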