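#' Call variants from aligned sequences
#'
#' Compares each sample sequence to the reference in the same alignment
#' frame.  Sequences must be as long as the (gapped) reference row: equal to
#' `ref$length` when gap-free, or padded with `-` where indels are present
#' (pass `ref_aligned` for a gapped reference row).  Every mismatching ACGT
#' column becomes a substitution; each run of gaps in a sample becomes one
#' deletion and each run of gaps in the reference one insertion (keyed by the
#' reference base before the run); ambiguity codes such as `N` yield no call.
#'
#' @param seqs Named character vector of sample sequences (or a
#'   `Biostrings::DNAStringSet`, or a single unnamed string).
#' @param ref A [mito_reference()] with a sequence.
#' @param population Population label stored with every call.
#' @param ref_aligned Optional gapped reference row aligning `seqs` to the
#'   reference frame (defaults to `ref$sequence`).
#' @return A variant profile tibble with columns `sample_id`, `population`,
#'   `position`, `end`, `kind`, `ref`, `alt`, `back_mutation`, ordered by
#'   sample then position.
#' @examples
#' ref <- random_reference(120, seed = 1)
#' s <- ref$sequence
#' substr(s, 10, 10) <- if (substr(s, 10, 10) == "A") "G" else "A"
#' call_variants(c(s1 = s), ref)
#' @export
call_variants <- function(seqs, ref, population = "cohort",
                          ref_aligned = NULL) {
  if (is.null(ref$sequence)) abort("reference sequence required")
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) "sample1"
                   else paste0("sample", seq_along(seqs))
  }
  ra <- toupper(ref_aligned %||% ref$sequence)
  rchars <- seq_chars(ra)
  refpos <- cumsum(rchars != "-")  # rCRS coordinate of each alignment column
  rows <- purrr::map(names(seqs), function(id) {
    s <- toupper(seqs[[id]])
    if (nchar(s) != nchar(ra)) {
      abort(sprintf(
        "sample '%s' length %d does not match alignment frame length %d",
        id, nchar(s), nchar(ra)))
    }
    schars <- seq_chars(s)
    calls <- list()

    is_sub <- rchars %in% BASES & schars %in% BASES & rchars != schars
    if (any(is_sub)) {
      calls$sub <- tibble(position = as.integer(refpos[is_sub]),
                          end = as.integer(refpos[is_sub]),
                          kind = "substitution",
                          ref = rchars[is_sub], alt = schars[is_sub],
                          back_mutation = FALSE)
    }
    del <- rle(schars == "-" & rchars != "-")
    if (any(del$values)) {
      ends <- cumsum(del$lengths); starts <- ends - del$lengths + 1L
      keep <- del$values
      calls$del <- tibble(
        position = as.integer(refpos[starts[keep]]),
        end = as.integer(refpos[ends[keep]]),
        kind = "deletion",
        ref = vapply(which(keep), function(i)
          chars_seq(rchars[seq(starts[i], ends[i])]), character(1)),
        alt = "", back_mutation = FALSE)
    }
    ins <- rle(rchars == "-" & schars != "-")
    if (any(ins$values)) {
      ends <- cumsum(ins$lengths); starts <- ends - ins$lengths + 1L
      keep <- ins$values
      anchor <- as.integer(refpos[pmax(starts[keep] - 1L, 1L)])
      calls$ins <- tibble(
        position = anchor, end = anchor, kind = "insertion",
        ref = vapply(anchor, function(p)
          if (p >= 1) substr(ref$sequence, p, p) else NA_character_,
          character(1)),
        alt = vapply(which(keep), function(i)
          chars_seq(schars[seq(starts[i], ends[i])]), character(1)),
        back_mutation = FALSE)
    }
    out <- bind_rows(calls)
    if (nrow(out) == 0L) return(mutate(empty_profile(), sample_id = character()))
    mutate(out, sample_id = id, population = population, .before = 1)
  })
  arrange(bind_rows(empty_profile(), rows), .data$sample_id, .data$position)
}

#' Site spectrum of a sample set
#'
#' Counts, for each distinct variant (position, kind, alternate allele), how
#' many samples carry it, and classifies sites as fixed (carried by all `n`
#' samples), singleton (one carrier) or shared (2..n-1 carriers).
#' Back-mutation assertions are reference-state records, not variants, and
#' are excluded from the counts; at a site like 4769 the carriers reported
#' are those of the derived allele, matching the usual variation-table
#' convention.  Insertions are shared only when both anchor and inserted
#' string match.
#'
#' @param profiles Variant profile tibble (>= 2 samples).
#' @param samples Optional character vector of all sample ids, needed when
#'   some samples carry no variants at all.
#' @return A `mito_spectrum` tibble: `position`, `kind`, `ref`, `alt`,
#'   `carriers`, `class`; attributes `n_samples` and `counts` (named vector
#'   with `total`, `fixed`, `shared`, `singleton`).
#' @export
site_spectrum <- function(profiles, samples = NULL) {
  p <- as_tibble(profiles)
  samples <- samples %||% unique(p$sample_id)
  n <- length(samples)
  if (n < 2L) abort("site_spectrum() needs at least 2 samples")
  v <- filter(p, !(.data$kind == "substitution" & .data$back_mutation))
  spec <- v |>
    group_by(.data$position, .data$end, .data$kind, .data$alt) |>
    summarise(ref = {i <- which(!is.na(.data$ref))
                     .data$ref[if (length(i)) i[1] else 1L]},
              carriers = dplyr::n_distinct(.data$sample_id),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$carriers >= n ~ "fixed",
      .data$carriers == 1L ~ "singleton",
      TRUE ~ "shared")) |>
    select("position", "end", "kind", "ref", "alt", "carriers", "class") |>
    arrange(.data$position, .data$alt)
  counts <- c(total = nrow(spec),
              fixed = sum(spec$class == "fixed"),
              shared = sum(spec$class == "shared"),
              singleton = sum(spec$class == "singleton"))
  structure(spec, class = c("mito_spectrum", class(spec)),
            n_samples = n, counts = counts)
}

#' Read a published-style variation matrix
#'
#' Reads the wide table layout used in mtDNA population reports: a first
#' column of row labels, position columns, one `CRS` row giving the
#' reference allele at each column, then one row per sample in which `.`
#' means reference state and a base a derived allele.  A `!` suffix on a
#' position column marks a back-mutation column: there, `.` is stored as an
#' explicit reference-state assertion (the background haplotype carries the
#' derived allele), per phylotree notation.
#'
#' @param path TSV file path.
#' @param population Population label for every sample.
#' @return Variant profile tibble (see [call_variants()] for columns).
#' @export
read_variant_matrix <- function(path, population = "cohort") {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  poscols <- names(m)[-1]
  back <- grepl("!$", poscols)
  positions <- as.integer(sub("!$", "", poscols))
  if (anyNA(positions)) abort("non-numeric position column in variant matrix")
  crs <- m[m[[1]] == "CRS", -1, drop = FALSE]
  if (nrow(crs) != 1L) abort("variant matrix needs exactly one CRS row")
  crs <- toupper(unlist(crs))
  rows <- m[m[[1]] != "CRS", , drop = FALSE]
  out <- purrr::map(seq_len(nrow(rows)), function(i) {
    id <- rows[[1]][i]
    cells <- toupper(unlist(rows[i, -1]))
    recs <- purrr::map(seq_along(cells), function(j) {
      cell <- cells[j]
      if (cell == "." && !back[j]) return(NULL)
      if (cell == ".") {  # asserted reversion to the reference-state allele
        return(tibble(position = positions[j], end = positions[j],
                      kind = "substitution", ref = NA_character_,
                      alt = crs[j], back_mutation = TRUE))
      }
      if (!cell %in% BASES) {
        abort(sprintf("unknown cell '%s' at position %d", cell, positions[j]))
      }
      tibble(position = positions[j], end = positions[j],
             kind = "substitution", ref = crs[j], alt = cell,
             back_mutation = FALSE)
    })
    mutate(bind_rows(recs), sample_id = id, population = population,
           .before = 1)
  })
  arrange(bind_rows(empty_profile(), out), .data$sample_id, .data$position)
}

#' Read and write variant profile tables
#'
#' Plain TSV with the profile columns (`sample_id`, `population`,
#' `position`, `end`, `kind`, `ref`, `alt`, `back_mutation`).
#'
#' @param path File path.
#' @param profiles Variant profile tibble.
#' @export
read_profile_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", population = "c", position = "i", end = "i",
    kind = "c", ref = "c", alt = "c", back_mutation = "l"))
}

#' @rdname read_profile_tsv
#' @export
write_profile_tsv <- function(profiles, path) {
  readr::write_tsv(as_tibble(profiles), path)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping the package's plain named character
#' vector convention.
#'
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
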