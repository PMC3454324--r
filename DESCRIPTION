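Package: hrescan
Title: Conserved Motif Scanning and Cooperativity Analysis for Hypoxia
    Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering transcription-factor binding motifs that
    co-occur with hypoxia response elements (RCGTG) in regulatory regions.
    Implements information-content-weighted position-weight-matrix scanning
    with MATCH-style threshold calibration (minFN, minFP, minSum),
    cross-species conservation filtering on multiple alignments,
    construction of core and matched background HRE region sets from
    ChIP-chip and expression evidence, tiling-array enriched-region calling,
    expression meta-analysis of hypoxic induction, and enrichment statistics
    (Fisher's exact test and correlation-based feature selection under
    repeated stratified cross-validation). A synthetic-data module generates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
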