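#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Maximum-likelihood corrected distance under the Tamura-Nei (1993) model,
#' which distinguishes purine transitions (A<->G, fraction `P1`), pyrimidine
#' transitions (C<->T, fraction `P2`) and transversions (fraction `Q`) under
#' unequal base frequencies.  With `gR = gA + gG`, `gY = gC + gT`:
#' \deqn{d = -\frac{2 g_A g_G}{g_R}\ln\!\left(1 - \frac{g_R P_1}{2 g_A g_G}
#'   - \frac{Q}{2 g_R}\right)
#'   - \frac{2 g_C g_T}{g_Y}\ln\!\left(1 - \frac{g_Y P_2}{2 g_C g_T}
#'   - \frac{Q}{2 g_Y}\right)
#'   - 2\left(g_R g_Y - \frac{g_A g_G g_Y}{g_R}
#'   - \frac{g_C g_T g_R}{g_Y}\right)\ln\!\left(1 - \frac{Q}{2 g_R g_Y}\right)}
#'
#' Base frequencies are estimated from the two sequences pooled (the
#' self-contained per-pair convention); pass `freqs` to impose
#' alignment-wide frequencies instead.  Alignment columns with a non-ACGT
#' symbol in either sequence are ignored pairwise.  When any logarithm
#' argument is non-positive the distance is saturated and `Inf` is returned
#' rather than an error.
#'
#' @param a,b Aligned sequences (strings of equal length).
#' @param freqs Optional named base frequency vector (`A`,`C`,`G`,`T`).
#' @return Non-negative distance (substitutions per site), or `Inf` when
#'   saturated.
#' @export
tn93_distance <- function(a, b, freqs = NULL) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) abort("sequences must be aligned (equal length)")
  use <- ca %in% BASES & cb %in% BASES
  ca <- ca[use]; cb <- cb[use]
  if (length(ca) == 0L) abort("no comparable ACGT sites")
  counts <- table(factor(ca, BASES), factor(cb, BASES))
  .tn93_from_counts(counts, freqs = freqs)
}

# distance from a 4x4 joint base-pair count matrix (rows = seq a, cols = seq b)
.tn93_from_counts <- function(counts, freqs = NULL) {
  L <- sum(counts)
  if (L == 0) return(NA_real_)
  p1 <- (counts["A", "G"] + counts["G", "A"]) / L
  p2 <- (counts["C", "T"] + counts["T", "C"]) / L
  same <- sum(diag(counts))
  q <- (L - same) / L - p1 - p2
  g <- if (is.null(freqs)) {
    (rowSums(counts) + colSums(counts)) / (2 * L)
  } else freqs[BASES] / sum(freqs[BASES])
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  if (gA * gG == 0 || gC * gT == 0 || gR * gY == 0) {
    # degenerate composition: fall back on whether any difference exists
    return(if (p1 + p2 + q == 0) 0 else Inf)
  }
  w1 <- 1 - gR * p1 / (2 * gA * gG) - q / (2 * gR)
  w2 <- 1 - gY * p2 / (2 * gC * gT) - q / (2 * gY)
  w3 <- 1 - q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(Inf)
  d <- -2 * gA * gG / gR * log(w1) -
    2 * gC * gT / gY * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
  max(d, 0)
}

#' TN93 distance matrix for an alignment
#'
#' @param seqs Named character vector of aligned sequences.
#' @param global_freqs Use alignment-wide base frequencies for every pair
#'   instead of the default per-pair pooled estimate.
#' @return A `dist` object (entries may be `Inf` where saturated).
#' @export
tn93_matrix <- function(seqs, global_freqs = FALSE) {
  n <- length(seqs)
  if (n < 2L) abort("need at least 2 sequences")
  freqs <- NULL
  if (global_freqs) {
    tab <- table(factor(unlist(strsplit(toupper(unlist(seqs)), "")), BASES))
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- BASES
  }
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      m[i, j] <- m[j, i] <- tn93_distance(seqs[[i]], seqs[[j]], freqs = freqs)
    }
  }
  stats::as.dist(m)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-criterion minimisation, via [ape::nj()]).
#' Negative branch lengths, an artefact of the least-squares step, are
#' clamped to zero with the total clamped deficit reported in a warning.
#'
#' @param dm A `dist` or symmetric matrix with >= 3 taxa; all entries must
#'   be finite.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- stats::as.dist(dm)
  if (attr(dm, "Size") < 3L) abort("neighbour joining needs >= 3 taxa")
  if (any(!is.finite(dm))) abort("distance matrix contains saturated (non-finite) entries")
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warn(sprintf("clamped %d negative branch length(s); total deficit %.3g",
                 sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

# --- alignment column classes -------------------------------------------
# Bootstrapping resamples alignment columns with replacement. mtDNA cohort
# alignments have very few distinct column patterns, so we aggregate columns
# into pattern classes once and draw multinomial class counts per replicate;
# per-pair joint base counts are then a single matrix product per pair.
.column_classes <- function(seqs) {
  n <- length(seqs)
  M <- do.call(rbind, lapply(seqs, function(s) {
    x <- match(seq_chars(s), BASES)
    x[is.na(x)] <- 0L
    x
  }))
  key <- apply(M, 2, paste0, collapse = ",")
  cls <- match(key, unique(key))
  C <- max(cls)
  counts <- tabulate(cls, nbins = C)
  patterns <- M[, match(seq_len(C), cls), drop = FALSE]  # n x C
  list(n = n, L = ncol(M), C = C, counts = counts, patterns = patterns,
       taxa = names(seqs))
}

# per-pair 16 x C indicator: row = joint (base_i, base_j) category, column =
# column class; zero column where either base is non-ACGT (ignored pairwise)
.pair_class_mats <- function(cc) {
  pairs <- utils::combn(cc$n, 2)
  lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    bi <- cc$patterns[i, ]; bj <- cc$patterns[j, ]
    ok <- bi > 0L & bj > 0L
    idx <- ifelse(ok, (bi - 1L) * 4L + bj, NA_integer_)
    Z <- matrix(0, 16L, cc$C)
    sel <- which(ok)
    Z[cbind(idx[sel], sel)] <- 1
    Z
  })
}

.tn93_matrix_from_weights <- function(cc, Zs, w) {
  n <- cc$n
  m <- matrix(0, n, n, dimnames = list(cc$taxa, cc$taxa))
  pairs <- utils::combn(n, 2)
  for (k in seq_len(ncol(pairs))) {
    c16 <- as.numeric(Zs[[k]] %*% w)
    counts <- matrix(c16, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
    i <- pairs[1, k]; j <- pairs[2, k]
    m[i, j] <- m[j, i] <- .tn93_from_counts(counts)
  }
  stats::as.dist(m)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the full-data TN93 + NJ tree, then resamples alignment columns
#' with replacement `reps` times, rebuilds the tree per replicate, and maps
#' the percentage of replicates containing each internal bipartition onto
#' the full-data tree's node labels (supports on the full-data topology, not
#' a majority-rule consensus).  Runs are reproducible: the same seed gives
#' identical supports.
#'
#' @param seqs Named character vector of aligned sequences (>= 3).
#' @param reps Number of bootstrap replicates (published mtDNA phylogenies
#'   conventionally use 500).
#' @param seed Integer seed (required).
#' @param global_freqs Passed to [tn93_matrix()] for the full-data tree.
#' @return A `phylo` tree whose `node.label` holds integer percentage
#'   supports; attribute `reps` records the replicate count.
#' @export
bootstrap_support <- function(seqs, reps = 500L, seed, global_freqs = FALSE) {
  if (missing(seed)) abort("a seed is required for reproducible bootstrap")
  if (reps < 1L) abort("reps must be >= 1")
  if (length(seqs) < 3L) abort("need >= 3 sequences")
  cc <- .column_classes(seqs)
  full_dm <- tn93_matrix(seqs, global_freqs = global_freqs)
  full <- nj_tree(full_dm)
  if (cc$C == 1L || all(full_dm == 0)) {
    warn("no variable sites: all bipartition supports set to 100")
    full$node.label <- rep(100L, full$Nnode)
    attr(full, "reps") <- as.integer(reps)
    return(full)
  }
  prob <- cc$counts / cc$L
  Zs <- .pair_class_mats(cc)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      w <- as.numeric(stats::rmultinom(1, cc$L, prob))
      dm <- suppressWarnings(.tn93_matrix_from_weights(cc, Zs, w))
      if (any(!is.finite(dm))) return(NULL)
      suppressWarnings(nj_tree(dm))
    })
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.integer(round(100 * counts / length(boots)))
  attr(full, "reps") <- as.integer(reps)
  full
}

#' Write a tree as newick
#'
#' @param tree A `phylo` tree (node labels, when present, are emitted as
#'   support values).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
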