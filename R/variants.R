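#' Parse a variant label into a variant record
#'
#' Understands the common mitochondrial variant label dialects, all in
#' 1-based rCRS coordinates:
#'
#' * `"m.1806T>C"` or `"1806T>C"` — substitution, reference T, alternate C;
#' * `"3909T"` — substitution to T (reference base unknown unless `ref`
#'   carries a sequence);
#' * `"4769!"` — back mutation: an assertion of the reference-state allele at
#'   a position where the background haplotype carries a derived allele
#'   (phylotree "!" notation);
#' * `"m.16295C insA"` (anchor base optional) — insertion anchored after
#'   position 16295;
#' * `"8281-8289d"` — deletion of the inclusive range.
#'
#' @param label Variant label string.
#' @param ref Optional [mito_reference()]; when it has a sequence, unknown
#'   reference alleles are filled in and declared reference alleles are
#'   checked against it.
#' @return One-row tibble with columns `position`, `end`, `kind`
#'   ("substitution", "insertion", "deletion"), `ref`, `alt`,
#'   `back_mutation`.  For insertions `ref` is the anchor base (or `NA`) and
#'   `alt` the inserted run; for deletions `alt` is `""`.  For back
#'   mutations `alt` is the asserted (reference-state) base when known.
#' @examples
#' parse_variant_label("m.1806T>C")
#' parse_variant_label("m.16295C insA")
#' @export
parse_variant_label <- function(label, ref = NULL) {
  if (!is_scalar_chr(label) || !nzchar(trimws(label))) {
    abort("variant label must be a non-empty string")
  }
  raw <- label
  x <- trimws(sub("^m\\.", "", trimws(label)))
  len <- if (!is.null(ref)) ref$length else NA_integer_
  base_at <- function(p) {
    if (!is.null(ref) && !is.null(ref$sequence)) substr(ref$sequence, p, p)
    else NA_character_
  }
  check_pos <- function(p) {
    if (p < 1) abort(sprintf("bad position in variant label '%s': %d", raw, p))
    if (!is.na(len)) check_positions(p, len, sprintf("position in '%s'", raw))
    p
  }
  out <- function(position, end, kind, ref_allele, alt, back = FALSE) {
    tibble(position = as.integer(position), end = as.integer(end),
           kind = kind, ref = ref_allele, alt = alt, back_mutation = back)
  }

  if (grepl("^\\d+[-]\\d+d(el)?$", x)) {
    m <- regmatches(x, regexec("^(\\d+)-(\\d+)d(el)?$", x))[[1]]
    from <- check_pos(as.integer(m[2])); to <- check_pos(as.integer(m[3]))
    if (to < from) abort(sprintf("deletion range reversed in '%s'", raw))
    del <- if (!is.null(ref) && !is.null(ref$sequence))
      substr(ref$sequence, from, to) else NA_character_
    return(out(from, to, "deletion", del, ""))
  }
  if (grepl("ins", x, fixed = TRUE)) {
    m <- regmatches(x, regexec("^(\\d+)([ACGTacgt])?\\s*ins([ACGTacgt]+)$", x))[[1]]
    if (length(m) == 0L) abort(sprintf("malformed insertion label '%s'", raw))
    p <- check_pos(as.integer(m[2]))
    anchor <- if (nzchar(m[3])) toupper(m[3]) else base_at(p)
    return(out(p, p, "insertion", anchor, toupper(m[4])))
  }
  if (grepl("^\\d+!$", x)) {
    p <- check_pos(as.integer(sub("!$", "", x)))
    return(out(p, p, "substitution", NA_character_, base_at(p), back = TRUE))
  }
  if (grepl("^\\d+[ACGTacgt]>[ACGTacgt]$", x)) {
    m <- regmatches(x, regexec("^(\\d+)([ACGTacgt])>([ACGTacgt])$", x))[[1]]
    p <- check_pos(as.integer(m[2]))
    r <- toupper(m[3]); a <- toupper(m[4])
    if (r == a) abort(sprintf("substitution with identical alleles in '%s'", raw))
    return(out(p, p, "substitution", r, a))
  }
  if (grepl("^\\d+[ACGTacgt]$", x)) {
    m <- regmatches(x, regexec("^(\\d+)([ACGTacgt])$", x))[[1]]
    p <- check_pos(as.integer(m[2]))
    a <- toupper(m[3])
    r <- base_at(p)
    if (!is.na(r) && r == a) {
      abort(sprintf("allele in '%s' equals the reference base %s", raw, r))
    }
    return(out(p, p, "substitution", r, a))
  }
  abort(sprintf("cannot parse variant label '%s'", raw))
}

#' Format a variant record as a canonical label
#'
#' Inverse of [parse_variant_label()].  Substitutions with a known reference
#' allele format as `"m.<pos><ref>><alt>"`, without one as `"<pos><alt>"`;
#' back mutations as `"<pos>!"`; insertions as `"m.<pos><ref> ins<seq>"`;
#' deletions as `"<start>-<end>d"`.
#'
#' @param variant Variant tibble (one or more rows).
#' @return Character vector of labels.
#' @export
format_variant_label <- function(variant) {
  v <- as_tibble(variant)
  vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    switch(r$kind,
      substitution =
        if (isTRUE(r$back_mutation)) paste0(r$position, "!")
        else if (!is.na(r$ref)) paste0("m.", r$position, r$ref, ">", r$alt)
        else paste0(r$position, r$alt),
      insertion =
        if (!is.na(r$ref)) paste0("m.", r$position, r$ref, " ins", r$alt)
        else paste0("m.", r$position, " ins", r$alt),
      deletion = paste0(r$position, "-", r$end, "d"),
      abort(sprintf("unknown variant kind '%s'", r$kind)))
  }, character(1))
}

# empty profile skeleton shared by callers
empty_profile <- function() {
  tibble(sample_id = character(), population = character(),
         position = integer(), end = integer(), kind = character(),
         ref = character(), alt = character(), back_mutation = logical())
}

#' Apply a variant profile to the reference sequence
#'
#' Reconstructs a sample's sequence from the reference and its variant
#' records.  Substitutions replace single bases, deletions remove their span
#' and insertions add bases after their anchor, so indels change the output
#' length.  Back-mutation assertions are no-ops at the sequence level (the
#' sample carries the reference base there).  The reference is not modified.
#'
#' @param ref A [mito_reference()] with a sequence.
#' @param profile Variant tibble for a single sample (a `sample_id` column,
#'   if present, must contain at most one id).
#' @return The sample sequence as a single string.
#' @export
apply_profile <- function(ref, profile) {
  if (is.null(ref$sequence)) abort("reference sequence required")
  p <- as_tibble(profile)
  if (nrow(p) == 0L) return(ref$sequence)
  if ("sample_id" %in% names(p) && dplyr::n_distinct(p$sample_id) > 1L) {
    abort("apply_profile() takes one sample; split multi-sample profiles first")
  }
  p <- p[!(p$kind == "substitution" & p$back_mutation), , drop = FALSE]
  if (nrow(p) == 0L) return(ref$sequence)
  check_positions(p$position, ref$length)
  # collision check: no two variants may touch the same reference base
  spans <- unlist(lapply(seq_len(nrow(p)), function(i) {
    if (p$kind[i] == "deletion") seq(p$position[i], p$end[i]) else p$position[i]
  }))
  sub_ins <- p$position[p$kind != "deletion"]
  dup <- unique(c(spans[duplicated(spans)], sub_ins[duplicated(sub_ins)]))
  if (length(dup)) {
    abort(paste("colliding variants at position(s):",
                paste(sort(dup), collapse = ", ")))
  }
  s <- seq_chars(ref$sequence)
  p <- p[order(p$position, decreasing = TRUE), ]
  for (i in seq_len(nrow(p))) {
    pos <- p$position[i]
    s <- switch(p$kind[i],
      substitution = { s[pos] <- p$alt[i]; s },
      deletion = s[-seq(pos, p$end[i])],
      insertion = append(s, seq_chars(p$alt[i]), after = pos),
      abort(sprintf("unknown variant kind '%s'", p$kind[i])))
  }
  chars_seq(s)
}
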