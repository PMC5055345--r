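Package: nucphase
Title: DNA-Encoded Rotational Nucleosome Positioning Signals and
    Transcription Start Site Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify rotational (10-bp helical phase) nucleosome
    positioning signals encoded in promoter DNA and to relate them to RNA
    polymerase II transcription initiation patterns. Provides dinucleotide
    (WW/SS/YY/RR) indicator tracks and sliding-window spectral scoring at a
    target frequency, degenerate 10-bp consensus motif enumeration and
    periodic enrichment scoring in +1 and genomic nucleosome DNA, MNase
    fragment midpoint (dyad) inference and aggregate occupancy profiles,
    CAGE micro-peak extraction and the Dispersion Index of initiation,
    promoter stratification by core promoter elements and CpG islands, and
    quantification of sequence-variant effects on initiation dispersion via
    a most-likely reference genome. A seeded synthetic-data generator
    emulates the statistical structure of all required inputs so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, Transcription, NucleosomePositioning, Sequencing
RoxygenNote: 7.3.3
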