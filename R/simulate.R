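#' Random reference genome with a synthetic gene map
#'
#' Generates a reproducible uniform-random circular genome and a synthetic
#' annotation laid out in proportion to a mitochondrial genome: a control
#' region wrapping the origin, one rRNA region, two protein genes sharing a
#' designed overlap (so overlap resolution is exercised), and a small tRNA.
#' Protein gene spans are multiples of 3.
#'
#' @param length Genome length in bases (>= 60; default 16,569).
#' @param seed Integer seed.
#' @return A [mito_reference()] with a sequence.
#' @export
random_reference <- function(length = 16569L, seed) {
  if (missing(seed)) abort("a seed is required")
  length <- as.integer(length)
  if (length < 60L) abort("length must be >= 60")
  sequence <- withr::with_seed(seed,
    chars_seq(sample(BASES, length, replace = TRUE)))
  frac <- function(x) max(1L, as.integer(floor(x * length)))
  ctrl_start <- length - frac(0.03) + 1L
  ctrl_end <- frac(0.03)
  rrna <- c(frac(0.05), frac(0.15))
  pa_start <- frac(0.20)
  pa_len <- 3L * max(6L, (frac(0.25) %/% 3L))
  pa_end <- pa_start + pa_len - 1L
  pb_start <- pa_end - 5L  # designed 6-base overlap with gene A
  pb_len <- 3L * max(4L, (frac(0.20) %/% 3L))
  pb_end <- min(pb_start + pb_len - 1L, length - frac(0.05))
  pb_end <- pb_start + ((pb_end - pb_start + 1L) %/% 3L) * 3L - 1L
  trna <- c(min(length - frac(0.04), pb_end + 2L), min(length - frac(0.04) + 2L, length))
  genes <- tibble(
    gene = c("control", "rRNA-1", "gene-A", "gene-B", "tRNA-1"),
    start = c(ctrl_start, rrna[1], pa_start, pb_start, trna[1]),
    end = c(ctrl_end, rrna[2], pa_end, pb_end, trna[2]),
    strand = "H",
    kind = c("control", "rRNA", "protein", "protein", "tRNA"),
    incomplete_stop = FALSE
  )
  mito_reference(sprintf("synthetic-%d", seed), length,
                 sequence = sequence, genes = genes)
}

#' Simulate a founder-effect mtDNA cohort
#'
#' Models the scenario behind a bottlenecked island population: every
#' sampled lineage descends from a single founder haplotype.  By default the
#' genealogy is a star — each of `n_samples` lineages independently
#' accumulates `Poisson(mu * L * generations)` substitutions placed
#' uniformly at random (without repeat positions within a lineage), so the
#' expected number of pairwise differences between two samples is
#' `2 * mu * L * generations` and all expectations stay analytic.  An
#' optional serial-founder mode (`bottlenecks`) inserts shared internal
#' branches: each scheduled stage draws that many ancestor lineages (with
#' replacement) from the previous stage, splitting the generations evenly
#' across stages, before the final samples are drawn.
#'
#' The defaults (`n_samples = 20`, `mu = 3e-6` per site per generation,
#' `generations = 30` on a 16,569-bp genome) put the cohort in the
#' low-diversity founder regime: about 1.5 mutations per lineage, about 3
#' mean pairwise differences, nucleotide diversity near 1.8e-4.
#'
#' @param ref A [mito_reference()] with a sequence.
#' @param n_samples Number of sampled lineages.
#' @param mu Substitution rate per site per generation.
#' @param generations Generations since the founder.
#' @param founder Founder haplotype as a variant profile tibble relative to
#'   `ref` (e.g. a motif's induced profile); `NULL` for the reference
#'   itself.
#' @param bottlenecks Optional integer vector of stage sizes for the
#'   serial-founder mode.
#' @param fixed_deletion Also place the 9-bp deletion (8281-8289) on the
#'   founder, to exercise indel handling (requires `ref$length >= 8289`).
#' @param seed Integer seed (required).
#' @return A `mito_cohort` list: `sequences` (named character vector),
#'   `profiles` (variants vs `ref`, population `"simulated"`), `truth`
#'   (tibble of introduced mutation events: `sample_id`, `position`, `from`,
#'   `to`, `stage`), `classes` (tibble `sample_id`, `class_id` by realised
#'   sequence identity), `config` (echo of all parameters).
#' @export
simulate_cohort <- function(ref, n_samples = 20L, mu = 3e-6,
                            generations = 30L, founder = NULL,
                            bottlenecks = NULL, fixed_deletion = FALSE,
                            seed) {
  if (missing(seed)) abort("a seed is required")
  if (is.null(ref$sequence)) abort("reference sequence required")
  if (n_samples < 1L) abort("n_samples must be >= 1")
  if (mu < 0) abort("mutation rate must be >= 0")
  if (mu * ref$length * generations > ref$length / 2) {
    abort("mutation load would saturate the genome; refusing to simulate")
  }
  fprof <- founder %||% empty_profile()
  if (fixed_deletion) {
    if (ref$length < 8289L) abort("reference too short for the 9-bp deletion")
    fprof <- bind_rows(as_tibble(fprof),
                       tibble(position = 8281L, end = 8289L,
                              kind = "deletion",
                              ref = substr(ref$sequence, 8281, 8289),
                              alt = "", back_mutation = FALSE))
  }
  founder_seq <- apply_profile(ref, fprof)
  L <- nchar(founder_seq)
  lambda_stage <- function(gens) mu * L * gens

  sim <- withr::with_seed(seed, {
    mutate_lineage <- function(chars, lam, id, stage) {
      k <- stats::rpois(1, lam)
      if (k == 0L) return(list(chars = chars, events = NULL))
      pos <- sample.int(length(chars), k)  # no repeat positions per lineage
      from <- chars[pos]
      to <- vapply(from, function(b) sample(other_bases(b), 1L),
                   character(1), USE.NAMES = FALSE)
      chars[pos] <- to
      list(chars = chars,
           events = tibble(sample_id = id, position = pos, from = from,
                           to = to, stage = stage))
    }
    fchars <- seq_chars(founder_seq)
    stages <- c(bottlenecks, n_samples)
    gens_each <- generations / length(stages)
    pool <- list(list(chars = fchars, events = NULL))
    for (s in seq_along(stages)) {
      last <- s == length(stages)
      ids <- if (last) sprintf("sim%02d", seq_len(n_samples))
             else sprintf("anc%d_%02d", s, seq_len(stages[s]))
      pool <- lapply(seq_len(stages[s]), function(i) {
        parent <- pool[[sample.int(length(pool), 1L)]]
        res <- mutate_lineage(parent$chars, lambda_stage(gens_each),
                              ids[i], stage = s)
        list(chars = res$chars,
             events = bind_rows(parent$events, res$events))
      })
    }
    names(pool) <- sprintf("sim%02d", seq_len(n_samples))
    pool
  })

  sequences <- vapply(sim, function(x) chars_seq(x$chars), character(1))
  truth <- bind_rows(lapply(names(sim), function(id) {
    ev <- sim[[id]]$events
    if (is.null(ev)) return(NULL)
    mutate(ev, sample_id = id)
  }))
  if (nrow(truth) == 0L) {
    truth <- tibble(sample_id = character(), position = integer(),
                    from = character(), to = character(), stage = integer())
  }
  # profiles are called against the reference frame; with a founder indel the
  # sample sequences are re-embedded by aligning the deletion gap explicitly
  if (L != ref$length && !fixed_deletion) {
    abort("founder profiles with indels are only supported via fixed_deletion")
  }
  profiles <- if (L == ref$length) {
    call_variants(sequences, ref, population = "simulated")
  } else {
    gap_aligned <- vapply(sequences, function(s) {
      paste0(substr(s, 1, 8280), strrep("-", ref$length - L),
             substr(s, 8281, L))
    }, character(1))
    call_variants(gap_aligned, ref, population = "simulated")
  }
  cls <- match(sequences, unique(sequences))
  structure(
    list(sequences = sequences, profiles = profiles,
         truth = truth,
         classes = tibble(sample_id = names(sequences), class_id = cls),
         config = list(reference = ref$id, length = ref$length,
                       n_samples = n_samples, mu = mu,
                       generations = generations,
                       bottlenecks = bottlenecks,
                       fixed_deletion = fixed_deletion, seed = seed)),
    class = "mito_cohort"
  )
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat(sprintf(
    "<mito_cohort> %d samples, %d mutation events, %d haplotype classes\n",
    length(x$sequences), nrow(x$truth), max(x$classes$class_id)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.fasta`, `truth.tsv` and `config.json` under `dir` for
#' provenance.
#'
#' @param cohort A `mito_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(cohort$sequences, file.path(dir, "cohort.fasta"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(cohort$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
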