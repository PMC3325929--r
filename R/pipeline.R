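#' Run the full cohort analysis pipeline
#'
#' Orchestrates the complete analysis on one or more population groups:
#' variant calling (when sequences are given), motif classification and
#' motif frequencies, per-population and pooled diversity statistics, a
#' TN93 neighbour-joining tree with bootstrap supports, a cross-population
#' variant frequency table, and a novelty screen against a local catalog.
#' All outputs are written under `out_dir`; identical inputs and seed give
#' byte-identical outputs.
#'
#' Input is either `profiles` (a variant profile tibble, or a named list of
#' profile TSV paths keyed by population) or `fasta` (a named list of
#' aligned FASTA paths keyed by population, called against `ref`).  The
#' tree stage needs sequences: with profile-only input and no reference
#' sequence, samples are realised on a seeded synthetic background so that
#' distances are driven by the recorded variant sites alone.
#'
#' @param profiles Variant profile tibble, or named list/vector of profile
#'   TSV paths.
#' @param fasta Named list/vector of aligned FASTA paths (alternative input).
#' @param ref A [mito_reference()]; defaults to [rcrs_reference()].
#' @param motifs A `mito_motifs` table; defaults to [maori_motifs()].
#' @param catalog Catalog tibble or TSV path; `NULL` skips the novelty
#'   stage.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed controlling the bootstrap and any synthetic
#'   background.
#' @param boot_reps Bootstrap replicates for the tree stage.
#' @param region Region filter passed to the frequency stage.
#' @param min_score Classification threshold, see [classify_haplotypes()].
#' @return A `mito_report` list: per-stage summaries, output file paths,
#'   package version and a configuration hash; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(profiles = NULL, fasta = NULL,
                         ref = rcrs_reference(), motifs = maori_motifs(),
                         catalog = NULL, out_dir, seed = 1L,
                         boot_reps = 100L,
                         region = c("all", "coding", "control"),
                         min_score = 1) {
  region <- match.arg(region)
  if (missing(out_dir)) abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(seed = seed, boot_reps = boot_reps, region = region,
                 min_score = min_score, reference = ref$id,
                 length = ref$length)
  cfg_hash <- rlang::hash(config)
  stage <- function(name, expr) {
    msg <- function(...) message(sprintf("[%s] %s", name, sprintf(...)))
    msg("start")
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  paths <- list()
  report <- list(tool = "mitopop",
                 version = as.character(utils::packageVersion("mitopop")),
                 config = config, config_hash = cfg_hash, stages = list())

  called <- stage("call", {
    if (!is.null(fasta)) {
      if (is.null(names(fasta))) abort("fasta paths must be named by population")
      seqs <- purrr::imap(as.list(fasta), function(path, pop) read_fasta(path))
      list(seqs = seqs,
           prof = bind_rows(purrr::imap(seqs, function(s, pop)
             call_variants(s, ref, population = pop))))
    } else if (is.character(profiles)) {
      list(seqs = NULL,
           prof = bind_rows(purrr::imap(as.list(profiles), function(path, pop)
             mutate(read_profile_tsv(path), population = pop))))
    } else if (is.data.frame(profiles)) {
      list(seqs = NULL, prof = as_tibble(profiles))
    } else {
      abort("either 'profiles' or 'fasta' input is required")
    }
  })
  seqs <- called$seqs
  prof <- called$prof
  # full roster of samples (a zero-variant sample has no profile rows)
  sample_tbl <- if (!is.null(seqs)) {
    bind_rows(purrr::imap(seqs, function(s, pop)
      tibble(sample_id = names(s), population = pop)))
  } else {
    distinct(select(prof, "sample_id", "population"))
  }
  paths$profiles <- file.path(out_dir, "profiles.tsv")
  write_profile_tsv(prof, paths$profiles)
  report$stages$call <- list(n_samples = nrow(sample_tbl),
                             n_records = nrow(prof))

  asg <- stage("classify", classify_haplotypes(prof, motifs,
                                               min_score = min_score,
                                               samples = sample_tbl$sample_id))
  mf <- motif_frequencies(prof, motifs, min_score = min_score,
                          samples = sample_tbl$sample_id)
  paths$assignments <- file.path(out_dir, "assignments.tsv")
  paths$motif_freqs <- file.path(out_dir, "motif_frequencies.csv")
  readr::write_tsv(as_tibble(asg), paths$assignments)
  readr::write_csv(as_tibble(mf), paths$motif_freqs)
  report$stages$classify <- list(n_assigned = sum(!is.na(asg$motif)))

  div <- stage("diversity", diversity_stats(prof, length = ref$length,
                                            samples = sample_tbl))
  paths$diversity <- file.path(out_dir, "diversity.csv")
  write_diversity_csv(div, paths$diversity)
  report$stages$diversity <- list(populations = div$population,
                                  n_ind = div$n_ind)

  tree <- stage("tree", {
    if (is.null(seqs)) {
      # distances use substitutions only (indels carry no TN93 information),
      # realised on the reference background or a seeded synthetic one
      base_ref <- if (!is.null(ref$sequence)) ref else
        mito_reference(ref$id, ref$length,
                       sequence = random_reference(ref$length,
                                                   seed = seed)$sequence,
                       genes = ref$genes)
      psub <- filter(prof, .data$kind == "substitution", !.data$back_mutation)
      ids <- sample_tbl$sample_id
      seqs <- vapply(ids, function(id)
        apply_profile(base_ref, psub[psub$sample_id == id, ]), character(1))
    } else {
      seqs <- unlist(unname(purrr::map(seqs, identity)))
      if (dplyr::n_distinct(nchar(seqs)) != 1L) {
        abort("input FASTA sequences are not in one alignment frame")
      }
    }
    bootstrap_support(seqs, reps = boot_reps, seed = seed)
  })
  paths$tree <- file.path(out_dir, "tree.nwk")
  write_newick(tree, paths$tree)
  report$stages$tree <- list(n_tips = length(tree$tip.label),
                             boot_reps = boot_reps)

  ft <- stage("freqs", frequency_table(
    prof, ref, region = region,
    group_sizes = vapply(split(sample_tbl$sample_id, sample_tbl$population),
                         base::length, integer(1))))
  paths$frequencies <- file.path(out_dir, "frequencies.csv")
  write_frequency_csv(ft, paths$frequencies)
  report$stages$freqs <- list(n_variants = dplyr::n_distinct(ft$variant))

  if (!is.null(catalog)) {
    cat_tbl <- if (is.character(catalog)) read_catalog(catalog) else catalog
    nov <- stage("novel", novelty_screen(prof, cat_tbl, ref))
    paths$novel <- file.path(out_dir, "novel_variants.tsv")
    readr::write_tsv(as_tibble(nov), paths$novel)
    report$stages$novel <- list(n_novel = nrow(nov))
  }

  report$outputs <- paths
  class(report) <- "mito_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(report)
}

#' @export
print.mito_report <- function(x, ...) {
  cat(sprintf("<mito_report> mitopop %s, config %s\n", x$version,
              x$config_hash))
  for (nm in names(x$outputs)) cat(sprintf("  %-12s %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}
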