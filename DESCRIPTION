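Package: epipanel
Title: Deep Targeted Epilepsy Gene Panel Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep targeted (gene panel) sequencing of
    infantile-onset epilepsy cohorts. Implements exon-level copy number
    variant detection from read depth via RPKM conversion and dual
    (within-sample, then across-sample) Z-score normalization with
    per-sample interquartile-range fences; population-frequency and
    low-allele-fraction (mosaic) candidate filtering of annotated variant
    tables; ACMG evidence combination into clinical classifications;
    barcode demultiplexing and allele counting for amplicon-based variant
    allele fraction validation; and cohort diagnostic-yield tabulation.
    A synthetic-data generator produces panel designs, coverage matrices
    with spiked CNVs, variant tables, barcoded amplicon read pools, and
    cohort tables with known ground truth, so that every stage is testable
    without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    Rsamtools,
    ggplot2,
    optparse,
    vcfR
Config/testthat/edition: 3
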