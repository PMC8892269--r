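Package: tdsilence
Title: Detection of Translation-Dependent Silencing Signatures from Ribosome
    Profiling, Small RNA, and 5'-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and rank discrete ribosome stalling events from
    ribosome-profiling alignments (P-site offset calibration from start-codon
    metagenes, codon occupancy, observed-over-expected stalling scores,
    transcriptome percentile ranking, codon dwell times), to profile small
    interfering RNA coverage by size class and strand with change-point onset
    detection, to tally 5'-hydroxyl RNA breakage ends from RACE clones, to
    score polysome association and quantitative-PCR relative expression and
    transposon copy number, and to scan coding sequences for codon adaptation,
    GC/GC3 content, G-quadruplex propensity and open-reading-frame content.
    A seeded synthetic-data generator emulates a two-isoform retroelement
    locus so that every analysis stage is testable end to end without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    methods,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
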