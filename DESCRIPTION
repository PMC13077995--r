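Package: ms2drs
Title: Dissecting Bacteriophage MS2 Transcription from Nanopore Direct RNA Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course Nanopore direct RNA sequencing
    (DRS) of the ssRNA coliphage MS2. Classifies viral reads into full-length,
    terminally anchored and subgenomic populations; computes 5-bp-window
    read start/end hotspot statistics with codon and AG-richness annotation;
    detects chimeric (template-switch) and foldback/copyback reads with a
    local-alignment segment finder and junction typing; and estimates
    per-site RNA modification stoichiometry with in-vitro-transcript (IVT)
    background subtraction, Fisher/Benjamini-Hochberg significance and
    temporal dynamic labels. Ships a synthetic-data generator that emulates
    every read population and modification table the pipeline consumes, with
    ground-truth labels, so all stages are testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    readr,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
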