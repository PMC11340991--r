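Package: numtogenesis
Title: Simulation, Detection, and Dynamics of Nuclear Mitochondrial DNA
    Insertions
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic nuclear mitochondrial DNA
    insertions (Numts) from whole-genome sequencing. Provides a seeded
    synthetic-data generator (genome models, planted insertion events,
    cohort call sets, longitudinal series, and junction-spanning read-pair
    evidence in SAM format), a discordant read-pair insertion caller with
    quality, support, and depth filtering, call-set merging with
    population/germline filtering and tissue-exclusive extraction,
    permutation-based hotspot testing over genomic bins,
    genic-content enrichment tests, longitudinal accumulation-rate
    estimation with slope comparison and effect sizes, and mitochondrial
    DNA copy-number estimation from sequencing coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
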