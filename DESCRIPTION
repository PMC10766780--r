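Package: airscreen
Title: In Silico Transcription-Factor Screening and Companion Analyses
    for Airway Epithelial Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks transcription factors by the differential expression of
    their protein-interaction neighborhoods across airway epithelial cell
    classes (basal versus non-basal) in labeled single-cell expression
    matrices, with permutation p-values over random gene sets. Also
    provides the companion ChIP-seq candidate-gene filter (exact-null
    position-weight-matrix site calling combined with a signed
    transcription-start-site window), peak annotation summaries
    (TSS density profile, genomic-region classification, read-depth
    comparison), an FFT-based ciliary-beat-frequency estimator for
    bead-displacement traces, and seeded synthetic-data generators with
    planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
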