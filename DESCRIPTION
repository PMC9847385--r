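Package: viralint
Title: Viral Integration Breakpoint Detection from Whole-Genome Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects viral sequences and viral-integration breakpoints in
    host whole-genome-sequencing alignments. Extracts single-mate-unmapped
    read pairs and soft-clipped fragments from a host alignment, aligns them
    to a viral reference panel with a seed-and-extend banded local aligner,
    screens viruses by per-sample read counts, assembles viral reads with a
    fixed-k de Bruijn graph assembler and scores genome completeness, calls
    and clusters host-genome integration breakpoints, annotates breakpoints
    against DNase-I hypersensitive sites, repeat classes and a gene model,
    and compares cohorts with Mann-Whitney U and t tests. Ships a
    paired-end integration simulator that generates host genomes, proviral
    insertions, reads, truth alignments and annotation tracks so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
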