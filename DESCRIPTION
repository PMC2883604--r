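Package: replitime
Title: Replication Timing Profiles, Replicon Maps, and Chromatin Feature
    Statistics from S-Phase Fraction Enrichment Arrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing DNA replication timing from tiling-array
    BrdU-immunoprecipitation enrichment ratios measured in sorted early, mid
    and late S-phase fractions. Provides replicate averaging and quantile
    normalization, fixed-window loess smoothing of genomic profiles,
    segmentation into eight replication-timing classes, detection of
    initiation and termination zones from profile extrema, precedence-based
    replicon boundary selection, replicon and replication-domain assembly,
    and the probe-, replicon- and gene-level statistics relating replication
    time to GC content, gene and transposable-element coverage, histone
    modifications, DNA methylation and gene expression. A stochastic
    origin-firing simulator generates synthetic chromosomes with full ground
    truth so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    limma,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
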