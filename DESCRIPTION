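Package: pingpongr
Title: Ping-Pong Signature Analysis for Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for piRNA-centric analysis of small RNA
    sequencing libraries: adapter clipping, rRNA/miRNA-hairpin depletion,
    length-based small RNA classification, ungapped transcript-level read
    alignment with explicit multi-mapper weighting, miRNA-hairpin and
    total-library normalisation, per-transposon sense/antisense
    quantification, the 5'-5' overlap histogram and ping-pong ratio with
    the 10A/1U signature, and replicate-aware differential abundance with
    Benjamini-Hochberg correction. Includes a synthetic small RNA read
    generator with ground-truth bookkeeping for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
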