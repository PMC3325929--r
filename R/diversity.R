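#' Collapse samples into haplotype classes
#'
#' Two samples belong to the same haplotype class iff their variant sets are
#' identical (substitutions and indels alike).  Back-mutation assertions
#' denote the reference state and therefore do not distinguish a sample from
#' one with no record at that position.
#'
#' @param profiles Variant profile tibble.
#' @param samples Optional full sample id vector, required when some samples
#'   carry no variants (they would otherwise be invisible).
#' @return A `mito_partition` tibble: `class_id`, `n_members`, `members`
#'   (list column of sample ids), `signature`; attribute `n_samples`.
#' @export
collapse_haplotypes <- function(profiles, samples = NULL) {
  p <- as_tibble(profiles)
  samples <- samples %||% unique(p$sample_id)
  if (length(samples) < 1L) abort("at least one sample required")
  v <- filter(p, !(.data$kind == "substitution" & .data$back_mutation))
  sig <- vapply(samples, function(id) {
    pv <- v[v$sample_id == id, , drop = FALSE]
    pv <- pv[order(pv$position, pv$kind, pv$alt), , drop = FALSE]
    paste(pv$position, pv$kind, pv$end, pv$alt, sep = ":", collapse = "|")
  }, character(1))
  classes <- tibble(sample_id = samples, signature = unname(sig)) |>
    group_by(.data$signature) |>
    summarise(n_members = n(), members = list(.data$sample_id),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_members), .data$signature) |>
    mutate(class_id = dplyr::row_number(), .before = 1)
  structure(classes, class = c("mito_partition", class(tibble())),
            n_samples = length(samples))
}

#' Haplotype diversity
#'
#' Nei's haplotype (gene) diversity.  The default unbiased estimator is
#' \deqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{p_i} the frequency of haplotype class \eqn{i}; `estimator =
#' "ml"` drops the \eqn{n/(n-1)} small-sample correction.
#'
#' @param x A `mito_partition` from [collapse_haplotypes()], or an integer
#'   vector of class multiplicities.
#' @param estimator `"unbiased"` (default) or `"ml"`.
#' @return Haplotype diversity in \[0, 1\].
#' @examples
#' haplotype_diversity(c(4, 4, 3, 2, 1, 1, 1, 1, 1, 1, 1))  # 0.916
#' @export
haplotype_diversity <- function(x, estimator = c("unbiased", "ml")) {
  estimator <- match.arg(estimator)
  mult <- if (inherits(x, "mito_partition")) x$n_members else as.numeric(x)
  if (any(mult < 1)) abort("class multiplicities must be positive")
  n <- sum(mult)
  if (n < 2) abort("haplotype diversity undefined for n < 2")
  h_ml <- 1 - sum((mult / n)^2)
  if (estimator == "ml") h_ml else n / (n - 1) * h_ml
}

# pairwise substitution differences between samples, from profiles.
# Returns a symmetric integer matrix over `samples`; positions listed in
# `exclude` are ignored.
pairwise_diffs <- function(profiles, samples, exclude = integer()) {
  v <- as_tibble(profiles) |>
    filter(.data$kind == "substitution", !.data$back_mutation,
           !(.data$position %in% exclude))
  positions <- sort(unique(v$position))
  n <- length(samples)
  d <- matrix(0L, n, n, dimnames = list(samples, samples))
  if (length(positions) == 0L || n < 2L) return(d)
  # allele matrix (samples x variable positions); 0 = reference state
  am <- matrix(0L, n, length(positions),
               dimnames = list(samples, positions))
  idx <- cbind(match(v$sample_id, samples), match(v$position, positions))
  am[idx] <- match(v$alt, BASES)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- sum(am[i, ] != am[j, ])
    }
  }
  d
}

# reference positions removed from the comparison because an indel touches
# them in any sample (complete-deletion convention)
indel_excluded_sites <- function(profiles) {
  dels <- filter(as_tibble(profiles), .data$kind == "deletion")
  unique(unlist(purrr::map2(dels$position, dels$end, seq)))
}

#' Nucleotide diversity
#'
#' Mean proportion of differing nucleotide sites per pair of sequences:
#' \deqn{\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2}\, L_\mathrm{eff}}}
#' where \eqn{d_{ij}} counts substitution differences between samples
#' \eqn{i} and \eqn{j}.  Following the complete-deletion convention, any
#' reference site covered by a deletion in any sample is excluded from both
#' the numerator and the effective length \eqn{L_\mathrm{eff}}; insertions
#' occupy no reference site and are ignored.
#'
#' @param profiles Variant profile tibble (>= 2 samples).
#' @param length Reference length in bases (16,569 for the rCRS).
#' @param samples Optional full sample id vector.
#' @return Per-site nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(profiles, length = 16569L, samples = NULL) {
  p <- as_tibble(profiles)
  samples <- samples %||% unique(p$sample_id)
  n <- base::length(samples)
  if (n < 2L) abort("nucleotide diversity undefined for n < 2")
  excl <- indel_excluded_sites(p)
  l_eff <- length - base::length(excl)
  if (l_eff <= 0) abort("no sites left after indel exclusion")
  d <- pairwise_diffs(p, samples, exclude = excl)
  sum(d[upper.tri(d)]) / choose(n, 2) / l_eff
}

#' Diversity summary per population
#'
#' Computes, for each population label and (optionally) the pooled sample,
#' the number of sequences, number of haplotype classes, haplotype diversity
#' `h` and nucleotide diversity `pi`.
#'
#' @param profiles Variant profile tibble with a `population` column.
#' @param length Reference length in bases.
#' @param pooled Add a pooled row over all populations.
#' @param pooled_label Label for the pooled row.
#' @param samples Optional tibble (`sample_id`, `population`) listing every
#'   sample, required when some samples carry no variant records.
#' @return A `mito_diversity` tibble: `population`, `n_ind`, `n_haplo`,
#'   `h`, `pi`.
#' @export
diversity_stats <- function(profiles, length = 16569L, pooled = TRUE,
                            pooled_label = "All populations",
                            samples = NULL) {
  p <- as_tibble(profiles)
  samples <- samples %||%
    distinct(select(p, "sample_id", "population"))
  ids_by_pop <- split(samples$sample_id, samples$population)
  one <- function(ids, label) {
    q <- p[p$sample_id %in% ids, , drop = FALSE]
    part <- collapse_haplotypes(q, samples = ids)
    n <- attr(part, "n_samples")
    tibble(population = label, n_ind = n, n_haplo = nrow(part),
           h = if (n >= 2) haplotype_diversity(part) else NA_real_,
           pi = if (n >= 2) nucleotide_diversity(q, length, samples = ids)
                else NA_real_)
  }
  out <- bind_rows(purrr::imap(ids_by_pop, one))
  if (pooled && base::length(ids_by_pop) >= 1L) {
    out <- bind_rows(out, one(samples$sample_id, pooled_label))
  }
  structure(out, class = c("mito_diversity", class(tibble())))
}

#' Write a diversity table as CSV
#'
#' Formats `h` to 3 and `pi` to 5 decimal places, the precision convention
#' of published mtDNA diversity tables.
#'
#' @param x A `mito_diversity` tibble.
#' @param path Output path.
#' @export
write_diversity_csv <- function(x, path) {
  out <- mutate(as_tibble(x),
                h = sprintf("%.3f", .data$h),
                pi = sprintf("%.5f", .data$pi))
  readr::write_csv(out, path)
  invisible(path)
}
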