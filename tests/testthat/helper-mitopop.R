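suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small hand-built reference: one clean protein gene (31..90, 20 codons),
# an rRNA, and a control region wrapping the origin.
toy_reference <- function(seed = 101, length = 120L) {
  seq <- withr::with_seed(seed,
    paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
           collapse = ""))
  genes <- tibble(
    gene = c("control", "rRNA-t", "prot-t"),
    start = c(111L, 10L, 31L),
    end = c(8L, 24L, 90L),
    strand = "H",
    kind = c("control", "rRNA", "protein"),
    incomplete_stop = FALSE
  )
  mito_reference("toy", length, sequence = seq, genes = genes)
}

# random substitution-only profile for a sample on a reference
random_sub_profile <- function(ref, sample_id, n_vars, population = "sim") {
  pos <- sort(sample.int(ref$length, n_vars))
  refb <- vapply(pos, function(p) substr(ref$sequence, p, p), character(1))
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  tibble(sample_id = sample_id, population = population,
         position = as.integer(pos), end = as.integer(pos),
         kind = "substitution", ref = refb, alt = unname(alt),
         back_mutation = FALSE)
}

# a motif (and the profile that induces it) anchored on actual reference
# bases, so that classification on called variants is exact
motif_from_reference <- function(ref, positions, name = "founder") {
  refb <- vapply(positions, function(p) substr(ref$sequence, p, p),
                 character(1))
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  labels <- paste0(positions, alt)
  motifs <- do.call(motif_table, stats::setNames(list(labels), name))
  profile <- tibble(sample_id = name, population = "sim",
                    position = as.integer(positions),
                    end = as.integer(positions),
                    kind = "substitution", ref = refb, alt = unname(alt),
                    back_mutation = FALSE)
  list(motifs = motifs, profile = profile)
}

# induced profile of one motif: its own requirements as variant records
induced_profile <- function(motifs, name, sample_id = name) {
  req <- motifs[motifs$motif == name, ]
  rows <- lapply(seq_len(nrow(req)), function(i) {
    r <- req[i, ]
    switch(r$type,
      allele = tibble(position = r$position, end = r$end,
                      kind = "substitution", ref = NA_character_,
                      alt = r$allele, back_mutation = FALSE),
      ref_state = tibble(position = r$position, end = r$end,
                         kind = "substitution", ref = NA_character_,
                         alt = NA_character_, back_mutation = TRUE),
      deletion = tibble(position = r$position, end = r$end,
                        kind = "deletion", ref = NA_character_, alt = "",
                        back_mutation = FALSE),
      insertion = tibble(position = r$position, end = r$end,
                         kind = "insertion", ref = NA_character_,
                         alt = r$allele, back_mutation = FALSE))
  })
  mutate(bind_rows(rows), sample_id = sample_id, population = "test",
         .before = 1)
}

# drop motif requirements at unobserved positions (e.g. when classifying a
# published matrix that prints only a subset of columns)
restrict_motifs <- function(motifs, positions) {
  out <- motifs[motifs$position %in% positions, ]
  keep <- out$motif %in% unique(out$motif)
  out <- out[keep, ]
  structure(out, class = class(motifs))
}

random_seq <- function(L) {
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

`%||%` <- function(x, y) if (is.null(x)) y else x
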