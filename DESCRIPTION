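Package: cpsar
Title: Size-Resolved Chromatin Particle Spectrum Analysis for MNase-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Chromatin particle spectrum analysis (CPSA) of paired-end
    micrococcal nuclease (MNase) sequencing data. Classifies protected DNA
    fragments by size into sub-nucleosomal (subNSP), mono-nucleosomal and
    multi-nucleosomal particles, builds midpoint, interpolated-coverage and
    size-by-position occupancy representations, and implements
    differential-digestion analyses (per-bin digestion correlation, fragile
    -1 nucleosome window tests), expression-linkage analyses (expression and
    kurtosis quartiles, subNSP versus expression fold-change trends) and
    genome-wide subNSP site calling with transcription-factor binding site
    aggregation. A seeded synthetic MNase-digestion simulator with planted
    nucleosome arrays, a labile -1 nucleosome, condition-responsive subNSP
    footprints and coupled expression tables provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    withr
Config/testthat/edition: 3
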