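Package: mpradav
Title: Allele-Specific Enhancer Activity Analysis for Massively Parallel
    Reporter Assays
Version: 0.1.0
Authors@R:
    person("MPRA", "Tools", email = "mpradav@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for massively parallel reporter
    assay (MPRA) studies of regulatory variants: barcode-oligo pairing
    recovery and quantification from raw reads, enhancer calling from
    cDNA/DNA barcode counts, differential allelic activity (DAV) testing
    with Benjamini-Hochberg control, context-specificity across cell types
    and stimuli, position-frequency-matrix motif disruption scoring and
    enrichment, functional annotation against peaks, chromatin loops,
    chromatin states and eQTLs, target-gene nomination by proximity, loops,
    co-accessibility and eQTLs, CROP-seq sgRNA assignment and knockdown
    testing, and polygenic risk score construction with decile odds
    ratios. Includes a full synthetic-data generator with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
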