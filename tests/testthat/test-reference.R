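test_that("variant labels parse to the right records and round-trip", {
  v <- parse_variant_label("m.1806T>C")
  expect_equal(v$position, 1806L)
  expect_equal(v$kind, "substitution")
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "C")
  expect_false(v$back_mutation)

  ins <- parse_variant_label("m.16295C insA")
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$position, 16295L)
  expect_equal(ins$ref, "C")
  expect_equal(ins$alt, "A")

  back <- parse_variant_label("4769!")
  expect_true(back$back_mutation)
  expect_equal(back$position, 4769L)

  del <- parse_variant_label("8281-8289d")
  expect_equal(del$kind, "deletion")
  expect_equal(c(del$position, del$end), c(8281L, 8289L))

  # canonical formatting round-trips through the parser
  for (lab in c("m.1806T>C", "m.16295C insA", "4769!", "8281-8289d",
                "3909T")) {
    v <- parse_variant_label(lab)
    expect_equal(parse_variant_label(format_variant_label(v)), v,
                 info = lab)
  }
})

test_that("malformed variant labels raise parse errors naming the token", {
  expect_error(parse_variant_label("m.0A>G"), "0")
  expect_error(parse_variant_label(""), "non-empty")
  expect_error(parse_variant_label("m.100X>G"), "100X>G")
  expect_error(parse_variant_label("m.100A>A"), "identical")
  expect_error(parse_variant_label("m.20000A>G", ref = rcrs_reference()),
               "range")
})

test_that("locate_feature maps published positions to their genes", {
  ref <- rcrs_reference()
  pick <- function(p) {
    f <- locate_feature(ref, p)
    f$gene[f$primary][1]
  }
  expect_equal(pick(9255), "COIII")
  expect_equal(pick(1185), "12SrRNA")
  expect_equal(pick(16295), "HVRI")
  expect_equal(pick(73), "HVRII")
  expect_equal(pick(15014), "Cyt b")
  expect_equal(pick(16500), "control")   # control region, outside HVRI
  expect_error(locate_feature(ref, 0), "range")
  expect_error(locate_feature(ref, 16570), "range")
})

test_that("overlapping genes report both with the conventional primary", {
  ref <- rcrs_reference()
  f <- locate_feature(ref, 8540)  # inside both ATP8 and ATP6
  expect_setequal(f$gene, c("ATP8", "ATP6"))
  expect_equal(f$gene[f$primary], "ATP6")
  f2 <- locate_feature(ref, 10762)
  expect_setequal(f2$gene, c("ND4L", "ND4"))
  expect_equal(f2$gene[f2$primary], "ND4")
})

test_that("codon arithmetic reproduces all published protein positions", {
  ref <- rcrs_reference()
  cases <- tibble::tribble(
    ~position, ~gene,    ~codon,
    3909,      "ND1",    201,
    4769,      "ND2",    100,
    5465,      "ND2",    332,
    6261,      "COI",    120,
    6719,      "COI",    272,
    6782,      "COI",    293,
    6905,      "COI",    334,
    7028,      "COI",    375,
    8860,      "ATP6",   112,
    8865,      "ATP6",   113,
    9123,      "ATP6",   199,
    9145,      "ATP6",   207,
    9255,      "COIII",  17,
    15014,     "Cyt b",  90
  )
  for (i in seq_len(nrow(cases))) {
    cp <- codon_position(ref, cases$gene[i], cases$position[i])
    expect_equal(cp$protein_position, cases$codon[i],
                 info = sprintf("position %d", cases$position[i]))
  }
  expect_equal(codon_position(ref, "ND1", 3307),
               list(protein_position = 1L, codon_offset = 0L))
  expect_error(codon_position(ref, "ND1", 5000), "outside")
  expect_error(codon_position(ref, "12SrRNA", 800), "not a protein")
})

test_that("codon coordinates are a bijection within a gene", {
  ref <- rcrs_reference()
  for (g in c("COI", "ND6")) {  # heavy and light strand
    row <- ref$genes[ref$genes$gene == g, ]
    pos <- seq(row$start, row$start + 59L)
    seen <- character()
    for (p in pos) {
      cp <- codon_position(ref, g, p)
      key <- paste(cp$protein_position, cp$codon_offset)
      expect_false(key %in% seen)
      seen <- c(seen, key)
      expect_equal(mitopop:::position_from_codon(row, cp$protein_position,
                                                 cp$codon_offset), p)
    }
  }
})

test_that("annotate_effect classifies constructed codon changes", {
  ref <- toy_reference()
  # overwrite codon 3 of the toy protein gene (positions 37-39) with CCT (Pro)
  s <- ref$sequence
  substr(s, 37, 39) <- "CCT"
  ref <- mito_reference("toy", ref$length, sequence = s, genes = ref$genes)
  eff <- annotate_effect(ref, tibble(position = 37L, end = 37L,
                                     kind = "substitution", ref = "C",
                                     alt = "T", back_mutation = FALSE))
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$aa_change, "P3S")  # written as <ref><codon><alt>
  expect_equal(eff$aa_ref, "P")
  expect_equal(eff$aa_alt, "S")
  # third-position wobble: CCT -> CCA still codes proline
  eff2 <- annotate_effect(ref, tibble(position = 39L, end = 39L,
                                      kind = "substitution", ref = "T",
                                      alt = "A", back_mutation = FALSE))
  expect_equal(eff2$effect, "synonymous")
  # rRNA positions carry no coding effect
  eff3 <- annotate_effect(ref, tibble(position = 12L, end = 12L,
                                      kind = "substitution", ref = "A",
                                      alt = "G", back_mutation = FALSE))
  expect_equal(eff3$effect, "not_applicable")
  # missing sequence is an explicit error, not a silent NA
  expect_error(
    annotate_effect(rcrs_reference(),
                    parse_variant_label("m.9255C>T")),
    "sequence required")
})

test_that("coding effects agree with whole-gene translation", {
  set.seed(202)
  ref <- toy_reference(seed = 303)
  g <- ref$genes[ref$genes$gene == "prot-t", ]
  code <- Biostrings::getGeneticCode("SGC1")
  translate_gene <- function(seq) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, g$start, g$end)),
      genetic.code = code, no.init.codon = TRUE))
  }
  aa_before <- translate_gene(ref$sequence)
  for (i in 1:50) {
    p <- sample(g$start:g$end, 1)
    b <- substr(ref$sequence, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    v <- tibble(position = as.integer(p), end = as.integer(p),
                kind = "substitution", ref = b, alt = alt,
                back_mutation = FALSE)
    eff <- annotate_effect(ref, v)
    mut <- apply_profile(ref, v)
    aa_after <- translate_gene(mut)
    expect_equal(eff$effect,
                 if (aa_before == aa_after) "synonymous" else "nonsynonymous",
                 info = sprintf("position %d %s>%s", p, b, alt))
    if (eff$effect == "nonsynonymous") {
      expect_equal(substr(aa_after, eff$protein_position,
                          eff$protein_position), eff$aa_alt)
    }
  }
})

test_that("apply_profile rebuilds sequences and respects indel arithmetic", {
  ref <- toy_reference()
  expect_equal(apply_profile(ref, tibble()), ref$sequence)
  one <- random_sub_profile(ref, "s1", 1)
  mut <- apply_profile(ref, one)
  expect_equal(sum(seq_chars(mut) != seq_chars(ref$sequence)), 1L)

  rc <- rcrs_reference(sequence = random_seq(16569))
  del <- parse_variant_label("8281-8289d", ref = rc)
  expect_equal(nchar(apply_profile(rc, del)), 16569L - 9L)

  ins <- parse_variant_label("m.50 insTT")
  expect_equal(nchar(apply_profile(ref, ins)), ref$length + 2L)

  clash <- dplyr::bind_rows(
    parse_variant_label("m.40A>G"), parse_variant_label("m.40A>C"))
  clash$ref <- substr(ref$sequence, 40, 40)
  expect_error(apply_profile(ref, clash), "collid")
})
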