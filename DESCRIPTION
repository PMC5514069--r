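Package: tradisr
Title: Transposon Insertion Sequencing Analysis for Bacterial Gene Essentiality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of transposon directed insertion-site sequencing (TraDIS/Tn-seq)
    libraries in bacteria: per-base insertion profiles from read alignments or plot
    tracks, per-gene insertion indices with 3'-end exclusion, a bimodal gamma mixture
    model of the insertion-index distribution with log2-likelihood-ratio essentiality
    calls, library quality analytics (rarefaction/saturation, replication-origin
    insertion gradient, A+T-richness bias), protein-family clustering with the Markov
    Cluster Algorithm for core-genome and essential-gene overlap analysis, and a
    seeded synthetic-library simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    fitdistrplus,
    jsonlite,
    stats,
    utils,
    graphics,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
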