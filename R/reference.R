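#' Reference mitochondrial genome model
#'
#' `mito_reference()` builds a reference genome object holding the coordinate
#' frame (1-based, inclusive), an optional base sequence, a gene annotation
#' table and the vertebrate mitochondrial genetic code.  `rcrs_reference()`
#' returns the standard human frame: the revised Cambridge Reference Sequence
#' (rCRS) coordinate system of length 16,569 with the bundled gene map (see
#' [mito_genes()]).  The rCRS base string itself is not bundled; supply one via
#' `sequence =` when coding-effect calls need actual codons.
#'
#' @param id Identifier for the reference.
#' @param length Genome length in bases.
#' @param sequence Optional uppercase nucleotide string of exactly `length`
#'   bases (gap-free).
#' @param genes Gene annotation tibble as returned by [mito_genes()] or
#'   [read_gene_table()].
#' @return An object of class `mito_reference`: a list with elements `id`,
#'   `length`, `sequence` (string or `NULL`), `genes` (tibble) and `code`
#'   (named character vector mapping codons to amino acids, vertebrate
#'   mitochondrial code).
#' @examples
#' ref <- rcrs_reference()
#' ref$length
#' @export
mito_reference <- function(id, length, sequence = NULL, genes = mito_genes()) {
  stopifnot(is.numeric(length), length >= 1)
  length <- as.integer(length)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      abort(sprintf("sequence length (%d) does not match declared length (%d)",
                    nchar(sequence), length))
    }
  }
  genes <- as_tibble(genes)
  # features may wrap the origin (control region): start > end is allowed
  if (any(genes$end > length | genes$start > length | genes$start < 1)) {
    abort("gene features must lie within [1, length]")
  }
  structure(
    list(id = id, length = length, sequence = sequence, genes = genes,
         code = mito_genetic_code()),
    class = "mito_reference"
  )
}

#' @rdname mito_reference
#' @export
rcrs_reference <- function(sequence = NULL) {
  mito_reference("rCRS", 16569L, sequence = sequence, genes = mito_genes())
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf("<mito_reference> %s: %d bp, %d features, sequence %s\n",
              x$id, x$length, nrow(x$genes),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (translation table 2), taken from Biostrings.
#'
#' @return Named character vector: names are codons, values one-letter amino
#'   acids (`*` = stop).
#' @export
mito_genetic_code <- function() {
  Biostrings::getGeneticCode("SGC1")
}

#' Bundled rCRS gene annotation
#'
#' Heavy-strand gene starts and ends for the 13 protein-coding genes, the two
#' rRNAs, the control region (wrapping the origin at 16024..576) and its
#' hypervariable sub-regions HVRI and HVRII, in 1-based inclusive rCRS
#' coordinates.  ND6 lies on the light strand.  Genes whose reading frame ends
#' in an incomplete stop codon (completed by polyadenylation) carry
#' `incomplete_stop = TRUE`, so their nucleotide span is not divisible by 3.
#'
#' Known same-strand overlaps (ATP8/ATP6, ND4L/ND4, ATP6/COIII boundary) are
#' retained; [locate_feature()] resolves which gene is reported as primary.
#'
#' @return Tibble with columns `gene`, `start`, `end`, `strand` ("H"/"L"),
#'   `kind` ("protein", "rRNA", "control"), `incomplete_stop`.
#' @export
mito_genes <- function() {
  tibble(
    gene = c("control", "HVRI", "HVRII", "12SrRNA", "16SrRNA",
             "ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
             "ND3", "ND4L", "ND4", "ND5", "ND6", "Cyt b"),
    start = c(16024L, 16024L, 57L, 648L, 1671L,
              3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L,
              10059L, 10470L, 10760L, 12337L, 14149L, 14747L),
    end = c(576L, 16383L, 372L, 1601L, 3229L,
            4262L, 5511L, 7445L, 8269L, 8572L, 9207L, 9990L,
            10404L, 10766L, 12137L, 14148L, 14673L, 15887L),
    strand = c(rep("H", 16L), "L", "H"),
    kind = c("control", "control", "control", "rRNA", "rRNA",
             rep("protein", 13L)),
    incomplete_stop = c(rep(FALSE, 5L),
                        TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                        TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
}

#' Read a gene annotation table from a BED-like file
#'
#' Tab-separated columns `gene`, `start`, `end`, `strand`, `kind` and
#' optionally `incomplete_stop`.  Coordinates are 1-based inclusive by
#' default; pass `zero_based = TRUE` for 0-based half-open input.
#'
#' @param path File path.
#' @param zero_based Interpret coordinates as 0-based half-open.
#' @export
read_gene_table <- function(path, zero_based = FALSE) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "start", "end", "strand", "kind")
  if (!all(need %in% names(g))) {
    abort(paste("gene table must have columns:", paste(need, collapse = ", ")))
  }
  if (zero_based) g <- mutate(g, start = .data$start + 1L)
  if (!"incomplete_stop" %in% names(g)) g$incomplete_stop <- FALSE
  g <- mutate(g, start = as.integer(.data$start), end = as.integer(.data$end))
  bad <- g$kind == "protein" & !g$incomplete_stop &
    (g$end - g$start + 1L) %% 3L != 0L
  if (any(bad)) {
    abort(paste("protein gene span not divisible by 3 (and not flagged",
                "incomplete_stop):", paste(g$gene[bad], collapse = ", ")))
  }
  g
}

# does a feature (possibly wrapping the origin) contain a position?
feature_contains <- function(start, end, position, len) {
  ifelse(start <= end,
         position >= start & position <= end,
         position >= start | position <= end)
}

# overlapping protein pairs: which gene's frame the annotation reports
.overlap_primary <- c("ATP8|ATP6" = "ATP6", "ND4L|ND4" = "ND4",
                      "ATP6|COIII" = "COIII")

#' Locate the gene feature at a reference position
#'
#' Returns all annotated features containing `position`, with a `primary`
#' flag resolving overlaps: for the known overlapping protein pairs the gene
#' whose reading frame the standard annotation uses wins (ATP6 over ATP8,
#' ND4 over ND4L, COIII over ATP6 at the shared boundary base); hypervariable
#' sub-regions (HVRI/HVRII) take precedence over the enclosing control region.
#' Positions in no feature return a single `intergenic` row.
#'
#' @param ref A [mito_reference()].
#' @param position 1-based reference coordinate (scalar).
#' @return Tibble of features (columns as [mito_genes()] plus `primary`).
#' @examples
#' locate_feature(rcrs_reference(), 9255)   # COIII
#' locate_feature(rcrs_reference(), 16295)  # HVRI (within the control region)
#' @export
locate_feature <- function(ref, position) {
  stopifnot(inherits(ref, "mito_reference"), length(position) == 1L)
  check_positions(position, ref$length)
  g <- ref$genes
  hit <- g[feature_contains(g$start, g$end, position, ref$length), ]
  if (nrow(hit) == 0L) {
    return(tibble(gene = "intergenic", start = NA_integer_, end = NA_integer_,
                  strand = NA_character_, kind = "intergenic",
                  incomplete_stop = FALSE, primary = TRUE))
  }
  hit$primary <- FALSE
  prot <- hit$gene[hit$kind == "protein"]
  if (length(prot) >= 2L) {
    pri <- .overlap_primary[paste(prot[1], prot[2], sep = "|")]
    if (is.na(pri)) pri <- .overlap_primary[paste(prot[2], prot[1], sep = "|")]
    hit$primary[hit$gene == (if (is.na(pri)) prot[1] else pri)] <- TRUE
  } else if (length(prot) == 1L) {
    hit$primary[hit$gene == prot] <- TRUE
  } else if (any(hit$gene %in% c("HVRI", "HVRII"))) {
    hit$primary[which(hit$gene %in% c("HVRI", "HVRII"))[1]] <- TRUE
  } else {
    hit$primary[1] <- TRUE
  }
  arrange(hit, dplyr::desc(.data$primary))
}

#' Codon index and offset of a position within a protein gene
#'
#' For a heavy-strand gene the protein (codon) position is
#' `floor((position - start) / 3) + 1` and the within-codon offset is
#' `(position - start) mod 3`.  For the light-strand gene (ND6) the frame
#' runs from `end` backwards on the reverse complement, so
#' `floor((end - position) / 3) + 1`.
#'
#' @param ref A [mito_reference()].
#' @param gene Gene name (must be a protein gene in `ref$genes`) or a one-row
#'   feature tibble.
#' @param position 1-based reference coordinate inside the gene.
#' @return List with integer elements `protein_position` and `codon_offset`
#'   (0, 1 or 2).
#' @examples
#' codon_position(rcrs_reference(), "COIII", 9255)  # codon 17
#' @export
codon_position <- function(ref, gene, position) {
  g <- if (is.character(gene)) {
    row <- ref$genes[ref$genes$gene == gene, ]
    if (nrow(row) == 0L) abort(sprintf("unknown gene '%s'", gene))
    row
  } else as_tibble(gene)
  if (g$kind != "protein") abort(sprintf("'%s' is not a protein gene", g$gene))
  if (position < g$start || position > g$end) {
    abort(sprintf("position %d outside gene %s [%d, %d]",
                  position, g$gene, g$start, g$end))
  }
  off0 <- if (g$strand == "L") g$end - position else position - g$start
  list(protein_position = off0 %/% 3L + 1L, codon_offset = off0 %% 3L)
}

# inverse of codon_position, used for property checks and codon extraction
position_from_codon <- function(gene_row, protein_position, codon_offset) {
  off0 <- (protein_position - 1L) * 3L + codon_offset
  if (gene_row$strand == "L") gene_row$end - off0 else gene_row$start + off0
}

#' Annotate the coding effect of a variant
#'
#' Classifies a substitution as synonymous or non-synonymous by translating
#' the affected reference codon and its mutated counterpart with the
#' vertebrate mitochondrial code.  Positions in rRNA, control or intergenic
#' territory, indels, and codons truncated by an incomplete stop are reported
#' as `not_applicable`.  For light-strand genes the codon is read off the
#' reverse complement.
#'
#' @param ref A [mito_reference()] whose `sequence` is present (required to
#'   recover the codon context).
#' @param variant One-row variant tibble as returned by
#'   [parse_variant_label()].
#' @return Tibble with columns `gene`, `kind`, `protein_position`,
#'   `codon_offset`, `effect` ("synonymous", "nonsynonymous",
#'   "not_applicable"), `aa_ref`, `aa_alt`, `aa_change` (e.g. `"P17S"`).
#' @export
annotate_effect <- function(ref, variant) {
  stopifnot(inherits(ref, "mito_reference"))
  v <- as_tibble(variant)
  feat <- locate_feature(ref, v$position)
  feat <- feat[feat$primary, ][1, ]
  na_row <- tibble(gene = feat$gene, kind = feat$kind,
                   protein_position = NA_integer_, codon_offset = NA_integer_,
                   effect = "not_applicable", aa_ref = NA_character_,
                   aa_alt = NA_character_, aa_change = NA_character_)
  if (feat$kind != "protein" || v$kind != "substitution" ||
      isTRUE(v$back_mutation)) {
    return(na_row)
  }
  if (is.null(ref$sequence)) {
    abort("reference sequence required to annotate coding effect")
  }
  cp <- codon_position(ref, feat, v$position)
  pos3 <- vapply(0:2, function(k) position_from_codon(feat, cp$protein_position, k),
                 numeric(1))
  if (any(pos3 < feat$start | pos3 > feat$end)) {
    # terminal codon truncated by an incomplete stop
    return(mutate(na_row, protein_position = cp$protein_position,
                  codon_offset = cp$codon_offset))
  }
  get_base <- function(p) substr(ref$sequence, p, p)
  codon_ref <- vapply(sort(pos3), get_base, character(1))
  codon_alt <- codon_ref
  idx <- match(v$position, sort(pos3))
  codon_alt[idx] <- toupper(v$alt)
  if (feat$strand == "L") {
    codon_ref <- revcomp_chars(codon_ref)
    codon_alt <- revcomp_chars(codon_alt)
  }
  code <- ref$code
  aa_ref <- unname(code[chars_seq(codon_ref)])
  aa_alt <- unname(code[chars_seq(codon_alt)])
  if (is.na(aa_ref) || is.na(aa_alt)) return(na_row)
  tibble(gene = feat$gene, kind = "protein",
         protein_position = cp$protein_position,
         codon_offset = cp$codon_offset,
         effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
         aa_ref = aa_ref, aa_alt = aa_alt,
         aa_change = if (aa_ref == aa_alt) NA_character_ else
           paste0(aa_ref, cp$protein_position, aa_alt))
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}
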