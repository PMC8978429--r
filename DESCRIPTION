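Package: beehive
Title: Small RNA Profiling, piRNA Cluster Calling and Differential
    Expression for Insect Reproductive Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for small RNA sequencing of insect
    reproductive tissues, modelled on honey bee (Apis mellifera)
    germline biology. Implements read-length and biotype profiling,
    density-based piRNA cluster identification with size-fraction,
    merge, minimum-length and strandedness rules, ping-pong and
    phasing biogenesis signatures (1U/10A bias, 10 nt 5' overlap
    Z-score, 3'-5' distance Z-score), positional classification of
    tRNA-derived fragments, strand-aware counting of putative piRNAs
    over transposable elements and genes, and a conditioned
    negative-binomial exact test for differential small RNA
    expression with threshold-based calls. Ships a synthetic-data
    generator that plants clusters, biases, ping-pong pairs, phased
    read trails and fold changes with a machine-readable truth
    manifest, so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
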