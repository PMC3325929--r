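#' Bundled Maori cohort variation matrix
#'
#' The published variation table for the 20 complete Maori mtDNA genomes
#' (coding-region and HVRII columns; the per-individual placement of HVRI
#' singletons was not printed and is not included).  Column 4769 is a
#' back-mutation column: the rCRS itself carries the rare allele A there,
#' the haplogroup-B background carries G, and the `.` cells are explicit
#' reversion assertions (the B4a1a1a3 marker).
#'
#' @return Variant profile tibble (population `"Maori"`, 20 samples).
#' @examples
#' prof <- maori_profiles()
#' glance(site_spectrum(prof))
#' @export
maori_profiles <- function() {
  read_variant_matrix(
    system.file("extdata", "maori_variation_matrix.tsv",
                package = "mitopop", mustWork = TRUE),
    population = "Maori")
}

#' Bundled synthetic known-variant catalog
#'
#' A small offline stand-in for a documented-variant database snapshot,
#' covering the haplogroup-defining and shared alleles of the bundled Maori
#' matrix but none of its novel variants.  It is synthetic: real novelty
#' screens should load a current database export via [read_catalog()].
#'
#' @return Catalog tibble (`position`, `alt`, `source`).
#' @export
synthetic_catalog <- function() {
  read_catalog(system.file("extdata", "known_variants_synthetic.tsv",
                           package = "mitopop", mustWork = TRUE))
}
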