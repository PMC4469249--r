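Package: tidysmallrna
Title: Tiered Annotation, IsomiR Profiling and Size-Class Analysis of
    Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for deep-sequenced small RNA libraries:
    3' adapter trimming with a short-adapter caveat, a four-tier
    homology-based miRNA classifier (offset-tolerant exact match,
    16-nt contiguous match after 10-nt prefix identity, Smith-Waterman
    local alignment score at least 70, putative miRNA), reads-per-million
    expression profiling, isomiR terminal-variant classification with
    seed-shift detection across tissues, ratio-based differential
    expression with fold and abundance filters, and characterization of
    repeat-derived putative piRNAs (26-31 nt). Includes a seeded
    synthetic-library generator with per-read ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
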