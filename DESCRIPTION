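Package: cistargets
Title: Cistrome-Transcriptome Integration for Direct Transcription Factor
    Target Nomination
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates transcription factor ChIP-seq peaks with
    histone-mark and ATAC-seq evidence and with knockdown
    differential-expression data to nominate candidate direct target
    genes.  Provides replicate peak intersection, genomic-feature
    annotation with signed nearest-TSS distances, rule-based
    classification of candidate regulatory elements (active/inactive
    promoters and enhancers from H3K27ac, H3K4me1 and H3K4me3
    co-occurrence), position weight matrix motif scanning with exact
    score-distribution p-values, fold-change/FDR filtering with
    two-siRNA concordance, a preranked gene-set enrichment score with
    permutation normalization, and a seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
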