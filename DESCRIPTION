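Package: dielsc
Title: Cluster Robustness, Marker Overlap and Di-Cistronic Transcripts
    for Diel Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for droplet single-cell RNA-seq studies of
    plant tissues harvested at end-of-day and end-of-night time points.
    Collapses barcode/UMI-tagged read alignments into digital expression
    matrices, applies transcript/gene/plastid cell filters, scores the
    robustness of cell clusters by repeated binomial read subsampling and
    cell co-occurrence, detects one-vs-rest Wilcoxon marker genes with
    fold-change and expressing-fraction thresholds, compares marker sets
    across clusterings with the Jaccard index, analyses day/night cluster
    composition and time-split markers, tests hypergeometric category
    enrichment, and calls di-cistronic (mRNA-tRNA read-through)
    transcripts from read-annotation overlap, including per-cluster
    enrichment of tRNA-like-sequence transcript isoforms. Ships a
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Matrix,
    igraph,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
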