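Package: mitopop
Title: Population Analysis of Complete Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of complete human
    mitochondrial genome cohorts in revised Cambridge Reference Sequence
    (rCRS) coordinates: variant calling from aligned sequences, parsing and
    annotation of variant labels (coding effect under the vertebrate
    mitochondrial code), motif-based haplogroup classification, Nei
    haplotype and nucleotide diversity, Tamura-Nei (TN93) distances with
    neighbour-joining trees and bootstrap support, cross-population variant
    frequency and novelty tables, and a founder-effect cohort simulator
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
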