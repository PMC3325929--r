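#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for mitopop result objects
#'
#' `tidy()` returns the per-record tibble underlying a result; `glance()`
#' returns a one-row summary.
#'
#' @param x A mitopop result object.
#' @param ... Unused.
#' @name mitopop-tidiers
NULL

#' @rdname mitopop-tidiers
#' @method tidy mito_spectrum
#' @export
tidy.mito_spectrum <- function(x, ...) as_tibble(x)

#' @rdname mitopop-tidiers
#' @method glance mito_spectrum
#' @export
glance.mito_spectrum <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble(n_samples = attr(x, "n_samples"),
         variable_sites = unname(cnt["total"]),
         fixed = unname(cnt["fixed"]), shared = unname(cnt["shared"]),
         singleton = unname(cnt["singleton"]))
}

#' @rdname mitopop-tidiers
#' @method tidy mito_partition
#' @export
tidy.mito_partition <- function(x, ...) {
  tidyr::unnest(select(as_tibble(x), "class_id", "members"),
                cols = "members") |>
    rename(sample_id = "members")
}

#' @rdname mitopop-tidiers
#' @method glance mito_partition
#' @export
glance.mito_partition <- function(x, ...) {
  tibble(n_samples = attr(x, "n_samples"), n_classes = nrow(x),
         h = haplotype_diversity(x))
}

#' @rdname mitopop-tidiers
#' @method tidy mito_assignment
#' @export
tidy.mito_assignment <- function(x, ...) as_tibble(x)

#' @rdname mitopop-tidiers
#' @method glance mito_assignment
#' @export
glance.mito_assignment <- function(x, ...) {
  tibble(n_samples = nrow(x),
         n_assigned = sum(!is.na(x$motif)),
         n_ambiguous = sum(x$ambiguous),
         n_motifs = dplyr::n_distinct(x$motif[!is.na(x$motif)]))
}

#' Plot methods for mitopop results
#'
#' `autoplot()` methods give quick ggplot2 views: carrier counts along the
#' genome for a site spectrum, motif fractions for a classification, a
#' population-by-variant frequency heatmap for a frequency table, and `h`
#' versus `pi` for a diversity table.
#'
#' @param object A mitopop result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name mitopop-autoplot
NULL

#' @rdname mitopop-autoplot
#' @method autoplot mito_spectrum
#' @export
autoplot.mito_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$carriers,
                               fill = .data$class)) +
    ggplot2::geom_col(width = 60) +
    ggplot2::labs(x = "rCRS position", y = "carriers",
                  title = "Site spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname mitopop-autoplot
#' @method autoplot mito_motif_freq
#' @export
autoplot.mito_motif_freq <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$motif, -.data$n),
                               y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of samples",
                  title = "Haplotype motif frequencies") +
    ggplot2::theme_minimal()
}

#' @rdname mitopop-autoplot
#' @method autoplot mito_freq_table
#' @export
autoplot.mito_freq_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$population,
                               y = stats::reorder(.data$variant,
                                                  -.data$position),
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "frequency",
                  title = "Rare-allele frequencies vs rCRS") +
    ggplot2::theme_minimal()
}

#' @rdname mitopop-autoplot
#' @method autoplot mito_diversity
#' @export
autoplot.mito_diversity <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pi, y = .data$h,
                               label = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = expression(pi ~ "(nucleotide diversity)"),
                  y = "h (haplotype diversity)") +
    ggplot2::theme_minimal()
}
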