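#' Cross-population variant frequency table
#'
#' Tabulates, for every distinct variant observed in any population, the
#' carrier count and frequency per population.  Frequencies are oriented to
#' the rare allele relative to the rCRS: ordinary variant rows count
#' carriers of the non-reference allele (so a haplogroup-defining allele can
#' have frequency 1), while back-mutation rows count carriers of the
#' asserted reference-state allele and are labelled from the derived
#' background allele (e.g. `G4769A`, the reversion to the rCRS's own rare
#' allele at 4769).
#'
#' @param profiles Variant profile tibble with a `population` column;
#'   samples with no variants must be added via `group_sizes`.
#' @param ref A [mito_reference()] (gene annotation; sequence optional).
#' @param group_sizes Optional named integer vector of samples per
#'   population (defaults to distinct sample ids seen per population).
#' @param region `"all"`, `"coding"` (protein genes only) or `"control"`.
#' @return A `mito_freq_table` tibble in long form: `gene`, `variant`,
#'   `position`, `population`, `carriers`, `n`, `frequency`, ordered by
#'   genomic position.  Use [write_frequency_csv()] for the wide
#'   per-population layout.
#' @export
frequency_table <- function(profiles, ref, group_sizes = NULL,
                            region = c("all", "coding", "control")) {
  region <- match.arg(region)
  p <- as_tibble(profiles)
  if (!"population" %in% names(p)) abort("profiles need a 'population' column")
  sizes <- group_sizes %||%
    vapply(split(p$sample_id, p$population), dplyr::n_distinct, integer(1))
  if (any(sizes == 0L)) {
    warn("dropping empty population group(s)")
    sizes <- sizes[sizes > 0L]
  }
  pops <- names(sizes)
  p <- filter(p, .data$population %in% pops)
  empty <- tibble(gene = character(), variant = character(),
                  position = integer(), population = character(),
                  carriers = integer(), n = integer(), frequency = numeric())
  if (nrow(p) == 0L) {
    return(structure(empty, class = c("mito_freq_table", class(tibble()))))
  }

  keyed <- mutate(p, key = paste(.data$position, .data$kind, .data$alt,
                                 .data$back_mutation, sep = "/"))
  sites <- keyed |>
    group_by(.data$key) |>
    summarise(position = .data$position[1], end = .data$end[1],
              kind = .data$kind[1],
              alt = .data$alt[1], back_mutation = .data$back_mutation[1],
              ref_allele = {i <- which(!is.na(.data$ref))
                            .data$ref[if (length(i)) i[1] else 1L]},
              .groups = "drop")
  # derived background allele per position, to label reversion rows
  derived_at <- keyed |>
    filter(.data$kind == "substitution", !.data$back_mutation) |>
    count(.data$position, .data$alt) |>
    group_by(.data$position) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("position", derived = "alt")

  gene_of <- function(pos) {
    f <- locate_feature(ref, pos)
    f <- f[f$primary, ][1, ]
    c(gene = f$gene, kind = f$kind)
  }
  ann <- t(vapply(sites$position, gene_of, character(2)))
  sites$gene <- ann[, "gene"]
  sites$gene_kind <- ann[, "kind"]
  if (region == "coding") sites <- filter(sites, .data$gene_kind == "protein")
  if (region == "control") sites <- filter(sites, .data$gene_kind == "control")

  if (nrow(sites) == 0L) {
    return(structure(empty, class = c("mito_freq_table", class(tibble()))))
  }
  sites <- left_join(sites, derived_at, by = "position") |>
    mutate(variant = dplyr::case_when(
      .data$kind == "substitution" & .data$back_mutation &
        !is.na(.data$derived) ~
        paste0(.data$derived, .data$position, .data$alt),
      .data$kind == "substitution" & !is.na(.data$ref_allele) ~
        paste0(.data$ref_allele, .data$position, .data$alt),
      .data$kind == "substitution" ~ paste0(.data$position, .data$alt),
      .data$kind == "insertion" ~ paste0(.data$position, " ins", .data$alt),
      TRUE ~ paste0(.data$position, "-", .data$end, "d")))

  carr <- keyed |>
    group_by(.data$key, .data$population) |>
    summarise(carriers = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  grid <- tidyr::expand_grid(key = sites$key, population = pops)
  out <- grid |>
    left_join(carr, by = c("key", "population")) |>
    mutate(carriers = tidyr::replace_na(.data$carriers, 0L),
           n = unname(sizes[.data$population]),
           frequency = .data$carriers / .data$n) |>
    left_join(select(sites, "key", "gene", "variant", "position"),
              by = "key") |>
    select("gene", "variant", "position", "population", "carriers", "n",
           "frequency") |>
    arrange(.data$position, .data$variant, .data$population)
  structure(out, class = c("mito_freq_table", class(tibble())))
}

#' Write a frequency table as a wide CSV
#'
#' One row per variant, one frequency column per population, mirroring the
#' layout of published cross-population variant tables.
#'
#' @param x A `mito_freq_table`.
#' @param path Output path.
#' @export
write_frequency_csv <- function(x, path) {
  wide <- as_tibble(x) |>
    select("gene", "variant", "position", "population", "frequency") |>
    tidyr::pivot_wider(names_from = "population",
                       values_from = "frequency") |>
    arrange(.data$position)
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read a known-variant catalog
#'
#' A catalog is a local snapshot of previously documented variants: TSV
#' with columns `position`, `alt` (`A`/`C`/`G`/`T` for substitutions,
#' `ins<seq>` for insertions, `del` for deletions) and optional `source`.
#'
#' @param path TSV path.
#' @return Tibble with columns `position`, `alt`, `source`.
#' @export
read_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(
    position = "i", alt = "c", .default = "c"))
  if (!all(c("position", "alt") %in% names(cat))) {
    abort("catalog needs 'position' and 'alt' columns")
  }
  if (!"source" %in% names(cat)) cat$source <- NA_character_
  distinct(cat, .data$position, .data$alt, .keep_all = TRUE)
}

catalog_key <- function(position, kind, alt) {
  paste(position, ifelse(kind == "substitution", alt,
                         ifelse(kind == "insertion", paste0("ins", alt),
                                "del")))
}

#' Screen observed variants for novelty against a catalog
#'
#' Reports every variant observed in at least one sample and absent from
#' the catalog, annotated with its gene, coding effect and carrier
#' percentage.  Back-mutation assertions are reference states, not novel
#' variants, and are never reported.  Coding effects require a reference
#' sequence; without one, `effect` and `protein_change` are `NA`.
#'
#' @param profiles Variant profile tibble.
#' @param catalog Catalog tibble from [read_catalog()] (may have zero rows).
#' @param ref A [mito_reference()].
#' @param samples Optional full sample id vector.
#' @return A `mito_novelty` tibble: `gene`, `variant`, `effect`,
#'   `protein_change`, `n_individuals`, `n_total`, `percentage`.
#' @export
novelty_screen <- function(profiles, catalog, ref, samples = NULL) {
  p <- as_tibble(profiles)
  samples <- samples %||% unique(p$sample_id)
  n_total <- length(samples)
  obs <- p |>
    filter(!(.data$kind == "substitution" & .data$back_mutation)) |>
    group_by(.data$position, .data$end, .data$kind, .data$alt) |>
    summarise(ref_allele = {i <- which(!is.na(.data$ref))
                            .data$ref[if (length(i)) i[1] else 1L]},
              n_individuals = dplyr::n_distinct(.data$sample_id),
              .groups = "drop")
  known <- catalog_key(catalog$position,
                       ifelse(grepl("^ins", catalog$alt), "insertion",
                              ifelse(catalog$alt %in% c("del", ""), "deletion",
                                     "substitution")),
                       sub("^ins", "", catalog$alt))
  novel <- obs[!(catalog_key(obs$position, obs$kind, obs$alt) %in% known), ,
               drop = FALSE]
  rows <- purrr::map(seq_len(nrow(novel)), function(i) {
    r <- novel[i, ]
    v <- tibble(position = r$position, end = r$end, kind = r$kind,
                ref = r$ref_allele, alt = r$alt, back_mutation = FALSE)
    eff <- if (r$kind == "substitution" && !is.null(ref$sequence)) {
      annotate_effect(ref, v)
    } else {
      f <- locate_feature(ref, r$position)
      f <- f[f$primary, ][1, ]
      tibble(gene = f$gene, effect = NA_character_,
             aa_change = NA_character_)
    }
    tibble(gene = eff$gene,
           variant = format_variant_label(v),
           position = r$position,
           effect = eff$effect,
           protein_change = eff$aa_change,
           n_individuals = r$n_individuals,
           n_total = n_total,
           percentage = 100 * r$n_individuals / n_total)
  })
  out <- bind_rows(tibble(gene = character(), variant = character(),
                          position = integer(),
                          effect = character(), protein_change = character(),
                          n_individuals = integer(), n_total = integer(),
                          percentage = numeric()), rows)
  structure(arrange(out, .data$position),
            class = c("mito_novelty", class(tibble())))
}
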