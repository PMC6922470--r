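Package: comics
Title: Stochastic Simulation of miRNA-mRNA Competition in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An iterative, discrete-molecule simulator of competition between
    microRNAs and mRNA transcripts in a single cell. Cell-level expression
    profiles are normalized to fixed molecule pools (by default 50,000 miRNAs
    and 25,000 transcripts), TargetScan-style cumulative weighted context++
    scores are converted to per-encounter binding probabilities, and an
    abundance-weighted sampling loop binds miRNAs to transcript binding sites
    and schedules delayed transcript removal with miRNA recycling. On top of
    the engine the package provides in-silico miRNA overexpression screens
    with fixed-pool renormalization, classification of genes that are stable
    or sensitive across miRNA perturbations, gene-set overlap statistics,
    comparison utilities for transcription-arrest time courses and validated
    interaction lists, randomized-network controls, and a synthetic fixture
    generator with an independent brute-force oracle for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
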