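Package: csidetect
Title: Conserved Signature Indels, Gene Neighborhoods and CXXC Motifs in
    Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects clade-specific conserved signature indels (CSIs) in
    gapped protein multiple sequence alignments given an in-group /
    out-group taxon partition: group-differential gap blocks are located,
    screened for conserved flanking sequence and clade specificity, mapped
    to ungapped reference-protein coordinates, and reported as a catalogue
    together with publication-style signature alignment blocks and
    validation segments for external homology screening.  Also predicts
    operons from genome annotations using strand, transcription direction
    and intergenic-distance rules, compares conserved gene-order (synteny)
    arrangements across genomes, and scans proteomes for CXXC
    (Cys-X-X-Cys) motifs.  A deterministic synthetic-data generator plants
    indels, gene clusters and motifs with exact ground truth so every
    stage is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    methods,
    stats,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
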