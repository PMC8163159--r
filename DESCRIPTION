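Package: rtamod
Title: tRNA Modification Calling from Reverse-Transcriptase Arrest and
    Misincorporation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies tRNA nucleotide-modification sites from
    chemically untreated tRNA-seq data (LOTTE-seq style libraries) using
    reverse-transcriptase arrest (RTa) intensity and base-misincorporation
    signatures. Builds non-redundant mature tRNA cluster references from gene
    annotations, assigns Sprinzl standard numbering by template alignment,
    computes per-position coverage, stop and base-composition profiles from
    alignments, calls candidate modification sites (RTa intensity >= 20%,
    coverage >= 10, Phred-scaled binomial confidence >= 20), suppresses TGIRT
    artifact signals, classifies calls against an RT-signature table and a
    known-position catalogue, aggregates results across developmental time
    points, and ships a deterministic 3'-anchored read simulator with planted
    modifications for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
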