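Package: captureDelta
Title: Differential Chromatin Conformation Analysis for Viewpoint-Anchored
    Capture-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects meso-scale and near-viewpoint changes in chromatin
    conformation from viewpoint-anchored Capture-C (or 4C-style) fragment
    count tracks. Provides in-silico restriction digestion into DpnII-like
    fragments, median-of-ratios size-factor normalization, binned difference
    tracks between conditions, a permutation test on contiguous constant-sign
    regions of the re-binned difference track, a distance-preserving
    mirror-pair sign-flip test for asymmetry around the viewpoint, replicate
    q-value merging and curation of locally most significant fragments,
    shared/specific interaction set classification, peak-overlap permutation
    enrichment, and a negative-binomial synthetic data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
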