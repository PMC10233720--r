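Package: phasePeak
Title: Oscillatory Gene Expression Phases and Transcription-Factor
    Binding Across the Nematode Molting Cycle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of oscillatory gene expression and
    transcription-factor ChIP-seq binding over the C. elegans molting
    cycle. Converts per-gene oscillation phases (degrees) to polar
    coordinates and to developmental hours on a molt-anchored larval
    clock, bins genes into early/middle/late phase classes, validates
    ChIP peak calls across replicates, assigns peaks to gene bodies and
    1 kb / 1-3 kb / 3-5 kb flanking bins by a minimum-overlap rule,
    computes TSS/TES-anchored body-scaled metagene signal profiles with
    confidence bands, and tests a regulated gene set for oscillation
    enrichment with a chi-squared goodness-of-fit test. Ships a seeded
    synthetic-data generator emulating the statistical structure of the
    real inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: ChIPSeq, GeneExpression, Annotation, Coverage, Sequencing
RoxygenNote: 7.3.3
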