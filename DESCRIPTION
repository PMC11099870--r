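Package: glucomem
Title: Glucose-Induced Transcriptional and Chromatin Accessibility Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integration pipeline for studying the persistence ("metabolic
    memory") of high-glucose-induced molecular alterations in endothelial
    cells after glucose normalization. Provides negative-binomial Wald
    differential expression with median-of-ratios normalization, a Poisson
    differential chromatin-accessibility test on consensus ATAC-seq peaks,
    annotation of accessible regions by genomic feature, enhancer calling by
    H3K4me1/H3K27ac co-overlap, enhancer-to-gene target assignment
    constrained to topologically associating domains with direction
    concordance, restoration classification under sulforaphane or NRF2
    overexpression, position-weight-matrix motif scanning and enrichment,
    gene-set over-representation, and a self-consistent synthetic-study
    generator with planted ground truth so every stage can be exercised and
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
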