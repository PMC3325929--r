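test_that("random references are reproducible and carry a usable gene map", {
  r1 <- random_reference(16569, seed = 5)
  r2 <- random_reference(16569, seed = 5)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(nchar(r1$sequence), 16569L)
  g <- r1$genes
  expect_true(any(g$kind == "protein"))
  expect_true(any(g$kind == "rRNA"))
  expect_true(any(g$kind == "control"))
  prot <- g[g$kind == "protein", ]
  expect_true(all((prot$end - prot$start + 1L) %% 3L == 0L))
  # the two protein genes share a designed overlap; other features do not
  expect_lt(prot$start[2], prot$end[1])
  expect_error(random_reference(30, seed = 1), ">= 60")
  expect_error(random_reference(500), "seed")
})

test_that("cohort simulation is seed-deterministic and honours rate zero", {
  ref <- random_reference(2000, seed = 8)
  c1 <- simulate_cohort(ref, n_samples = 10, mu = 1e-5, generations = 20,
                        seed = 31)
  c2 <- simulate_cohort(ref, n_samples = 10, mu = 1e-5, generations = 20,
                        seed = 31)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$truth, c2$truth)

  c0 <- simulate_cohort(ref, n_samples = 10, mu = 0, generations = 20,
                        seed = 31)
  expect_true(all(c0$sequences == ref$sequence))
  expect_equal(nrow(c0$profiles), 0L)
  part <- collapse_haplotypes(c0$profiles, samples = names(c0$sequences))
  expect_equal(nrow(part), 1L)
  expect_equal(haplotype_diversity(part), 0)
  expect_equal(nucleotide_diversity(c0$profiles, ref$length,
                                    samples = names(c0$sequences)), 0)

  expect_error(simulate_cohort(ref, mu = 1, generations = 10, seed = 1),
               "saturate")
})

test_that("mutation counts follow the Poisson expectation", {
  ref <- random_reference(2000, seed = 13)
  gens <- 10; mu <- 2e-4  # lambda = 4 per lineage
  co <- simulate_cohort(ref, n_samples = 200, mu = mu, generations = gens,
                        seed = 7)
  lambda <- mu * 2000 * gens
  counts <- table(factor(co$truth$sample_id, names(co$sequences)))
  mean_obs <- mean(counts)
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean_obs - lambda), 3 * se)
})

test_that("the cohort profiles equal the recorded mutation truth", {
  ref <- random_reference(3000, seed = 23)
  co <- simulate_cohort(ref, n_samples = 30, mu = 5e-5, generations = 10,
                        seed = 11)
  for (id in names(co$sequences)) {
    ev <- co$truth[co$truth$sample_id == id, ]
    pr <- co$profiles[co$profiles$sample_id == id, ]
    expect_setequal(pr$position, ev$position)
    expect_equal(pr$alt[order(pr$position)], ev$to[order(ev$position)])
  }
  # realised haplotype classes are consistent with sequence identity
  expect_equal(co$classes$class_id,
               match(co$sequences, unique(co$sequences)))
})

test_that("nucleotide diversity increases with the mutation rate", {
  ref <- random_reference(2000, seed = 29)
  mean_pi <- function(mu) {
    mean(vapply(1:20, function(s) {
      co <- simulate_cohort(ref, n_samples = 10, mu = mu, generations = 10,
                            seed = 1000 + s)
      nucleotide_diversity(co$profiles, ref$length,
                           samples = names(co$sequences))
    }, numeric(1)))
  }
  pis <- vapply(c(1e-5, 5e-5, 2e-4), mean_pi, numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("mean pairwise differences regress on rate with slope 2 L g", {
  ref <- random_reference(16569, seed = 41)
  gens <- 30
  rates <- c(5e-7, 1e-6, 2e-6, 4e-6)
  mpd <- vapply(seq_along(rates), function(i) {
    co <- simulate_cohort(ref, n_samples = 100, mu = rates[i],
                          generations = gens, seed = 500 + i)
    d <- mitopop:::pairwise_diffs(co$profiles, names(co$sequences))
    mean(d[upper.tri(d)])
  }, numeric(1))
  slope <- stats::coef(stats::lm(mpd ~ rates))[["rates"]]
  expected <- 2 * 16569 * gens
  expect_lt(abs(slope - expected) / expected, 0.2)
})

test_that("the fixed 9-bp deletion option exercises indel handling", {
  ref <- random_reference(16569, seed = 47)
  co <- simulate_cohort(ref, n_samples = 5, mu = 1e-6, generations = 10,
                        fixed_deletion = TRUE, seed = 3)
  expect_true(all(nchar(co$sequences) == 16569L - 9L))
  dels <- co$profiles[co$profiles$kind == "deletion", ]
  expect_equal(unique(dels$position), 8281L)
  expect_equal(unique(dels$end), 8289L)
  expect_equal(dplyr::n_distinct(dels$sample_id), 5L)
})

test_that("serial-founder bottlenecks create shared derived variants", {
  ref <- random_reference(5000, seed = 53)
  co <- simulate_cohort(ref, n_samples = 40, mu = 5e-5, generations = 30,
                        bottlenecks = c(2L), seed = 19)
  sp <- site_spectrum(co$profiles, samples = names(co$sequences))
  # with 2 ancestors and 40 descendants, ancestral-branch mutations are
  # carried by many samples: shared (or fixed) sites must appear
  expect_true(any(sp$carriers >= 2))
  expect_identical(
    co$sequences,
    simulate_cohort(ref, n_samples = 40, mu = 5e-5, generations = 30,
                    bottlenecks = c(2L), seed = 19)$sequences)
})

test_that("cohort artefacts serialise to plain text outputs", {
  ref <- random_reference(1000, seed = 59)
  co <- simulate_cohort(ref, n_samples = 4, mu = 1e-4, generations = 5,
                        seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.fasta")))
  back <- read_fasta(file.path(dir, "cohort.fasta"))
  expect_equal(back, co$sequences)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$n_samples, 4L)
})
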