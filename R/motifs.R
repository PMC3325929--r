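#' Read a haplotype motif table
#'
#' Motif tables define named haplotypes by their required states at a set of
#' rCRS positions, in the wide layout of published marker tables: one row
#' per motif, one column per position.  Cell symbols:
#'
#' * a base (`A`/`C`/`G`/`T`) — the derived allele is required;
#' * `.` — an active reference-state assertion: the sample must NOT carry a
#'   derived allele there (this is how sibling motifs such as B4a1a1c and
#'   B4a1a1a5, differing only by 16247 presence/absence, are separated);
#' * `-` or an empty cell — no requirement at that position;
#' * `d` — the column name is a range `start-end` and its deletion is
#'   required (e.g. the Polynesian-motif 9-bp deletion, column `8281-8289`);
#' * `ins<seq>` — an insertion of `<seq>` anchored after the position.
#'
#' An optional `parent` column records nesting and is carried through.
#'
#' @param path TSV path; first column holds motif names.
#' @return A `mito_motifs` tibble with one row per requirement: `motif`,
#'   `position`, `end`, `type` ("allele", "ref_state", "deletion",
#'   "insertion"), `allele`, `parent`.
#' @export
read_motif_table <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (nrow(m) == 0L) abort("motif table is empty")
  names(m)[1] <- "motif"
  parent <- if ("parent" %in% names(m)) m$parent else rep(NA_character_, nrow(m))
  m <- m[, !(names(m) %in% "parent"), drop = FALSE]
  if (anyDuplicated(m$motif)) {
    abort(paste("duplicate motif name(s):",
                paste(unique(m$motif[duplicated(m$motif)]), collapse = ", ")))
  }
  poscols <- names(m)[-1]
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    reqs <- purrr::map(poscols, function(cn) {
      cell <- m[[cn]][i]
      if (is.na(cell) || cell %in% c("-", "")) return(NULL)
      rng <- as.integer(strsplit(cn, "-", fixed = TRUE)[[1]])
      pos <- rng[1]; end <- if (length(rng) > 1L) rng[2] else rng[1]
      if (anyNA(rng)) abort(sprintf("non-numeric position column '%s'", cn))
      if (cell == ".") {
        tibble(position = pos, end = end, type = "ref_state",
               allele = NA_character_)
      } else if (toupper(cell) %in% BASES) {
        tibble(position = pos, end = end, type = "allele",
               allele = toupper(cell))
      } else if (tolower(cell) %in% c("d", "del")) {
        tibble(position = pos, end = end, type = "deletion",
               allele = NA_character_)
      } else if (grepl("^ins[ACGTacgt]+$", cell)) {
        tibble(position = pos, end = end, type = "insertion",
               allele = toupper(sub("^ins", "", cell)))
      } else {
        abort(sprintf("unknown state symbol '%s' for motif %s at %s",
                      cell, m$motif[i], cn))
      }
    })
    req <- bind_rows(reqs)
    if (nrow(req) == 0L) {
      abort(sprintf("motif '%s' has no requirements", m$motif[i]))
    }
    if (anyDuplicated(req$position)) {
      abort(sprintf("motif '%s' repeats a position", m$motif[i]))
    }
    mutate(req, motif = m$motif[i], parent = parent[i], .before = 1)
  })
  structure(bind_rows(rows), class = c("mito_motifs", class(tibble())))
}

#' Build a motif table from requirement labels
#'
#' Programmatic alternative to [read_motif_table()]: each motif is a
#' character vector of requirement labels in the variant-label dialect
#' (`"1185T"`, `"4769!"`, `"8281-8289d"`, `"16295 insA"`).
#'
#' @param ... Named character vectors, one per motif.
#' @param parent Optional named character vector of parent motif names.
#' @export
motif_table <- function(..., parent = NULL) {
  defs <- list(...)
  if (length(defs) == 0L) abort("motif table is empty")
  if (is.null(names(defs)) || any(!nzchar(names(defs)))) {
    abort("every motif must be named")
  }
  if (anyDuplicated(names(defs))) abort("duplicate motif name(s)")
  rows <- purrr::imap(defs, function(labels, nm) {
    req <- purrr::map(labels, function(lab) {
      v <- parse_variant_label(lab)
      type <- if (v$kind == "substitution" && v$back_mutation) "ref_state"
        else switch(v$kind, substitution = "allele", insertion = "insertion",
                    deletion = "deletion")
      tibble(position = v$position, end = v$end, type = type,
             allele = if (type %in% c("allele", "insertion")) v$alt
                      else NA_character_)
    })
    req <- bind_rows(req)
    if (anyDuplicated(req$position)) {
      abort(sprintf("motif '%s' repeats a position", nm))
    }
    mutate(req, motif = nm,
           parent = (parent[[nm]] %||% NA_character_), .before = 1)
  })
  structure(bind_rows(rows), class = c("mito_motifs", class(tibble())))
}

#' Bundled B4a1a1 marker motifs
#'
#' The four B4a1a1 sub-haplotype motifs observed in the Maori cohort
#' (B4a1a1c, B4a1a1a, B4a1a1a3, B4a1a1a5; B4a1a1a3 is defined by 1185T plus
#' the 4769 reference-state reversion) together with a `Polynesian-motif`
#' entry (the 8281-8289 9-bp deletion plus the 16189/16217/16247/16261
#' control-region substitutions).  Sources differ on whether the classical
#' Polynesian motif has three or four control-region sites; all four are
#' included here and the entry carries no reference-state assertions so that
#' it remains compatible with its descendant motifs.
#'
#' @return A `mito_motifs` tibble (see [read_motif_table()]).
#' @export
maori_motifs <- function() {
  read_motif_table(system.file("extdata", "b4a1a1_motifs.tsv",
                               package = "mitopop", mustWork = TRUE))
}

# one requirement against one sample's variant records
requirement_met <- function(req, pv) {
  at <- pv[pv$position == req$position, , drop = FALSE]
  derived <- at[at$kind == "substitution" & !at$back_mutation, , drop = FALSE]
  switch(req$type,
    allele = any(derived$alt == req$allele),
    ref_state = nrow(derived) == 0L,
    deletion = any(at$kind == "deletion" & at$end == req$end),
    insertion = any(at$kind == "insertion" & at$alt == req$allele),
    FALSE)
}

requirement_label <- function(req) {
  switch(req$type,
    allele = paste0(req$position, req$allele),
    ref_state = paste0(req$position, "!"),
    deletion = paste0(req$position, "-", req$end, "d"),
    insertion = paste0(req$position, " ins", req$allele))
}

#' Classify samples into haplotype motifs
#'
#' Scores every sample against every motif.  A motif is satisfied when all
#' its requirements are met; the best assignment is the fully satisfied
#' motif with the most requirements (the most specific), with lexicographic
#' tie-breaking flagged `ambiguous`.  When no motif is fully satisfied the
#' best-scoring partial match is reported, but `motif` is set only if its
#' score reaches `min_score` (default 1: exact matches only, the convention
#' of published haplotype assignments).
#'
#' @param profiles Variant profile tibble.
#' @param motifs A `mito_motifs` table.
#' @param min_score Minimum fraction of requirements met for a partial match
#'   to be assigned.
#' @param samples Optional full sample id vector (for variant-free samples).
#' @return A `mito_assignment` tibble: `sample_id`, `motif` (NA if
#'   unassigned), `matched`, `n_required`, `score`, `missed`
#'   (";"-separated unmet requirement labels), `ambiguous`.
#' @export
classify_haplotypes <- function(profiles, motifs, min_score = 1,
                                samples = NULL) {
  if (!inherits(motifs, "mito_motifs") || nrow(motifs) == 0L) {
    abort("non-empty mito_motifs table required")
  }
  p <- as_tibble(profiles)
  samples <- samples %||% unique(p$sample_id)
  motif_split <- split(as_tibble(motifs), motifs$motif)
  rows <- purrr::map(samples, function(id) {
    pv <- p[p$sample_id == id, , drop = FALSE]
    scored <- purrr::imap(motif_split, function(mreq, nm) {
      met <- vapply(seq_len(nrow(mreq)), function(i)
        requirement_met(mreq[i, ], pv), logical(1))
      tibble(motif = nm, matched = sum(met), n_required = nrow(mreq),
             score = sum(met) / nrow(mreq),
             missed = paste(vapply(which(!met), function(i)
               requirement_label(mreq[i, ]), character(1)), collapse = ";"))
    })
    scored <- bind_rows(scored)
    full <- scored[scored$score == 1, , drop = FALSE]
    if (nrow(full) > 0L) {
      top <- full[full$n_required == max(full$n_required), , drop = FALSE]
      top <- top[order(top$motif), , drop = FALSE]
      best <- top[1, ]
      best$ambiguous <- nrow(top) > 1L
    } else {
      best <- scored[order(-scored$score, scored$motif), ][1, ]
      best$ambiguous <- FALSE
      if (best$score < min_score) best$motif <- NA_character_
    }
    mutate(best, sample_id = id, .before = 1)
  })
  structure(bind_rows(rows),
            class = c("mito_assignment", class(tibble())))
}

#' Motif frequencies in a sample set
#'
#' Classifies all samples (see [classify_haplotypes()]) and tabulates counts
#' and fractions per motif; samples with no exact assignment are reported on
#' an `unclassified` row, so fractions sum to 1.
#'
#' @inheritParams classify_haplotypes
#' @return A `mito_motif_freq` tibble: `motif`, `n`, `fraction`.
#' @export
motif_frequencies <- function(profiles, motifs, min_score = 1,
                              samples = NULL) {
  asg <- classify_haplotypes(profiles, motifs, min_score = min_score,
                             samples = samples)
  n_total <- nrow(asg)
  tab <- asg |>
    mutate(motif = ifelse(is.na(.data$motif), "unclassified", .data$motif)) |>
    count(.data$motif, name = "n") |>
    mutate(fraction = .data$n / n_total) |>
    arrange(dplyr::desc(.data$n), .data$motif)
  structure(tab, class = c("mito_motif_freq", class(tibble())),
            n_samples = n_total)
}
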