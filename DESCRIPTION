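Package: mirlifespan
Title: Lifespan Classification of Blood microRNA Expression from qPCR Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for TaqMan Low Density Array (TLDA) microRNA
    profiles across the human lifespan. Normalizes threshold-cycle (Ct)
    values against an endogenous control (delta-Ct), applies a
    detectability rule for censored (non-amplified) assays, classifies
    every panel miRNA into five age-related expression classes by
    rank-sum testing with Bonferroni correction, detects post-adulthood
    aging-diminished expression with Benjamini-Hochberg FDR control and
    age correlation, scans miRBase genomic annotations for cytoband
    hot spots of same-class miRNAs, and provides contingency-table and
    network-score utilities. Includes a synthetic qPCR panel simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
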