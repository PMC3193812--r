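Package: mitorecomb
Title: Repeat-Mediated Recombination and Rearrangement Analysis for Plant
    Mitochondrial Genomes
Version: 0.9.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises double-strand-break-driven
    rearrangements in circular plant mitochondrial genomes from short
    paired-end reads.  Provides genome self-alignment discovery of repeat
    pairs, a circular-aware read mapper, clustering of discordant read
    pairs into recombination junctions with support filtering, inference
    of strand-invasion polarity and parental-form fate (class I/II) from
    flanking read depth, gene-conversion analysis at nonidentical repeats,
    and a cross-accession panel pipeline (threshold SNP calling,
    NHEJ/REC/DEL structural-variant typing, distance phylogeny with
    bootstrap and group assignment).  A fully deterministic synthetic-data
    generator emulates the sequencing libraries and accession panels the
    methods were designed for, so every stage is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
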