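Package: eislands
Title: Calling Heterochromatin LOCKs and Euchromatin Islands from
    Tiling-Array H3K9me2 Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments large organized chromatin K9-modification domains
    (LOCKs) from probe-level log2(ChIP/Input) tiling-array tracks, detects
    euchromatin islands (EIs) inside LOCK bodies with a smoothing,
    bottom-percentile threshold and filtering algorithm, and quantifies EI
    overlap with genomic feature sets (CTCF, DHS, TSS, CpG islands, PMDs)
    using length-matched random-interval permutation nulls with Bonferroni
    correction.  Includes partial quantile normalization of log-ratio
    tracks, gene/TSS annotation utilities, signal meta-profiles, and a
    synthetic-data generator that plants LOCKs, islands and enriched
    feature sets with full ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    tibble,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
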