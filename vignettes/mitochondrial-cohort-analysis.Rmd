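---
title: "Analysing complete mtDNA cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing complete mtDNA cohorts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
library(dplyr)
```

mitopop analyses cohorts of complete human mitochondrial genomes: variant
profiles against the revised Cambridge Reference Sequence (rCRS),
motif-based haplogroup classification, diversity statistics, a TN93 +
neighbour-joining phylogeny, cross-population frequency tables and a
novelty screen, plus a founder-effect simulator that makes the whole chain
testable without any external sequence download.  This vignette records the
statistical model behind each stage, the tunable parameters and their
defaults, and the design decisions that were genuinely open.

## Coordinates, variant records and the back-mutation convention

All positions are 1-based, inclusive, in the 16,569-bp rCRS frame — the
frame in which mtDNA variation is universally reported.  A variant record
is one row of a tibble: `position`, `end`, `kind` (substitution, insertion,
deletion), `ref`, `alt`, `back_mutation`.  Insertions anchor after their
position and never consume reference coordinates; deletions span
`position..end`.

Back mutations need care in haplogroup work: phylotree marks them `!`, and
the rCRS itself carries rare alleles at a handful of positions (4769 is the
canonical example: the haplogroup-B background carries G, the rCRS A).  A
back-mutation record is an *active assertion of the reference-state allele*
on a derived background, not the mere absence of a call.  We store it
explicitly (`back_mutation = TRUE`, `alt` = the asserted base) because two
analyses treat it asymmetrically:

* the site spectrum and haplotype collapsing treat it as reference state
  (it is not a variant, and a sample asserting it is sequence-identical to
  one with no record there);
* motif classification and the frequency table treat it as information:
  B4a1a1a3 is *defined* by the 4769 reversion, and the published frequency
  convention reports the reversion carriers (7/20 = 0.35) under the label
  `G4769A`.

## Gene annotation and coding effects

The bundled gene map carries the 13 protein genes, both rRNAs, the
wrapping control region (16024..576) and its HVRI/HVRII sub-regions, with
heavy-strand starts such as ND1 3307, ND2 4470, COI 5904, ATP6 8527, COIII
9207, Cyt b 14747.  These constants are verifiable in-repo: the codon index
`floor((pos − start)/3) + 1` reproduces all twelve published protein
positions for the cohort's coding variants (201, 100, 332, 120, 272, 293,
334, 375, 112, 113, 199, 207) and the codon-17/codon-90 placements of the
novel COIII and Cyt b variants — this is the acceptance suite's anchor.
Genes whose reading frame ends in an incomplete, polyadenylation-completed
stop codon are flagged; a variant in such a truncated terminal codon is
reported `not_applicable` rather than guessed.  For the overlapping pairs
(ATP8/ATP6, ND4L/ND4, and the single shared base at the ATP6/COIII
boundary) both features are returned and the gene whose reading frame the
standard annotation uses is flagged primary.  ND6 is the one light-strand
gene; its codons are read on the reverse complement from the feature's end.
Effects are classified by translating the reference and mutated codon under
the vertebrate mitochondrial code (Biostrings translation table 2), and a
property test checks 50 random substitutions against a brute-force
whole-gene translation.

The rCRS base string itself is *not* bundled — no acceptance quantity needs
it, and the package stays fully buildable offline.  Operations that need
actual codons (effect annotation, sequence realisation) accept a
user-supplied or synthetic sequence; the published Table-style fixtures are
pure coordinate data.

One annotation discrepancy is left as the data have it: the published
variation table marks 5465 as synonymous while also listing an amino-acid
change for it in one row; the package reports whatever the code table
yields for the supplied sequence and does not force agreement with either
reading.

## Motif classification

A motif table maps haplotype names to required states: derived alleles,
indels, and reference-state assertions.  Assertions are checked actively —
the sample must *not* carry a derived allele there — because sibling
haplotypes can differ only by presence/absence of one site (B4a1a1c vs
B4a1a1a5 differ only at 16247).  The best assignment is the fully satisfied
motif with the most requirements; ties are broken lexicographically and
flagged ambiguous.  The default acceptance threshold for partial matches is
1.0 (exact), matching how published assignments are made; `min_score`
relaxes it.

The bundled table holds the four B4a1a1 sub-haplotype rows plus a
Polynesian-motif entry (the 8281–8289 9-bp deletion with the
16189/16217/16247/16261 control-region sites).  Sources disagree on whether
the classical motif has three or four control-region SNPs; we include all
four.  The Polynesian-motif row carries no reference-state assertions so it
stays compatible with descendant motifs; in the four-row block, `.` cells
are assertions, exactly as in the published marker table.

Classification is invariant to variants at positions no motif references —
a property test adds random non-motif singletons and checks the assignment
is unchanged.

## Diversity statistics

Samples collapse into haplotype classes by exact variant-set identity
(indels included; assertions excluded as argued above).  Haplotype
diversity uses Nei's unbiased estimator

$$h = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),$$

the estimator used by the standard DNA-polymorphism software this
analysis mirrors; the maximum-likelihood flavour without the small-sample
factor is available via `estimator = "ml"`.  Nucleotide diversity is the
mean pairwise proportion of differing sites,

$$\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2} L_\mathrm{eff}},$$

with the complete-deletion convention: any reference site covered by a
deletion in any sample leaves both the numerator and $L_\mathrm{eff}$.
For a cohort in which the 9-bp deletion is fixed this exclusion does not
perturb within-cohort $\pi$.  Insertions occupy no reference site and are
ignored.  A brute-force all-pairs Hamming count over realised sequences
serves as the oracle in tests.

One published quantity is deliberately reproduced only at the summary
level: the cohort's printed variation matrix omits the per-individual HVRI
singleton columns, so the full 11-class partition (h = 0.916) cannot be
rebuilt cell-by-cell.  The printed columns yield 10 classes with
multiplicities {6,4,2,2,1,1,1,1,1,1}; the 0.916 value is checked by
evaluating the estimator on the unique 11-class multiplicity vector
consistent with it, (4,4,3,2,1,1,1,1,1,1,1), and the whole-cohort regime is
covered by the simulator property below.

## TN93 distances, neighbour joining, bootstrap

The Tamura–Nei (1993) distance distinguishes purine transitions $P_1$,
pyrimidine transitions $P_2$ and transversions $Q$ under unequal base
frequencies $g$:

$$d = -\frac{2 g_A g_G}{g_R}\ln w_1 - \frac{2 g_C g_T}{g_Y}\ln w_2
 - 2\Big(g_R g_Y - \frac{g_A g_G g_Y}{g_R} - \frac{g_C g_T g_R}{g_Y}\Big)\ln w_3$$

with $w_1 = 1 - g_R P_1 / 2 g_A g_G - Q/2g_R$, $w_2$ symmetric for
pyrimidines, and $w_3 = 1 - Q/2 g_R g_Y$.  Any non-positive logarithm
argument means the pair is saturated; the distance is returned as `Inf`
rather than an error, and tree building refuses non-finite matrices
explicitly.  Base frequencies are pooled from the two sequences of each
pair by default — a self-contained convention that needs no alignment-wide
state — with `global_freqs = TRUE` switching to alignment-wide estimates.
On two-sequence alignments the conventions coincide, which is how the
implementation is cross-checked against an independent one (`ape`'s) to
machine precision; in the equal-frequency, equal-transition limit the
formula collapses to Kimura's two-parameter distance, checked in closed
form.

Trees come from standard neighbour joining on the distance matrix, with
negative least-squares branch lengths clamped to zero and the deficit
reported.  NJ is consistent on additive matrices; tests verify exact
topology and length recovery up to 8 leaves, and against an exhaustive
3-topology length optimum for 4 taxa.

Bootstrap supports resample alignment columns with replacement.  Since a
cohort alignment has few distinct column patterns, columns are aggregated
into pattern classes once and each replicate draws a multinomial class
weighting — algebraically identical to column resampling, orders of
magnitude faster.  Supports are the percentage of replicate trees
containing each internal bipartition of the full-data tree, mapped onto
that topology ("consensus tree" is read as supports-on-the-full-tree, the
common reading; a majority-rule alternative would change the topology shown
but not the supports of shared splits).  The default depth is the
conventional 500 replicates; the seed is mandatory and two runs with the
same seed are byte-identical.  A zero-variation alignment yields a warned
star with all supports defined as 100.  Whether published distance figures
included the control region or the 9-bp deletion is typically unstated;
the default here is substitutions only over the whole molecule.

## The founder-effect simulator

`simulate_cohort()` models what a bottlenecked island colonisation leaves
behind: every sampled lineage descends from one founder haplotype.  The
default genealogy is a *star* — lineages independent given the founder —
because the within-B4a1a1 structure of such cohorts is nearly star-like and
because a star keeps every expectation analytic: mutation counts per
lineage are Poisson($\mu L g$), mean pairwise differences are $2\mu L g$,
and regressing observed differences on $\mu$ must recover slope $2Lg$
(checked within 20% at n = 100).  An optional serial-founder mode
(`bottlenecks`) inserts shared ancestral branches by resampling ancestor
lineages at scheduled stages.

Defaults are chosen once to match the low-diversity founder regime the
package targets: $L = 16{,}569$, $n = 20$ lineages, $g = 30$ generations,
$\mu = 3\times10^{-6}$ per site per generation, i.e. $\lambda \approx 1.5$
mutations per lineage, $\approx 3$ mean pairwise differences and $\pi
\approx 1.8\times10^{-4}$ — the order of magnitude observed in the Maori
cohort, ten-fold below worldwide populations ($\pi \approx 1.7\times
10^{-3}$, emulated by $\mu = 2.8\times10^{-5}$ in the separation test).
The acceptance property averages $\pi$ over 20 seeded cohorts and requires
it within a factor of 2 of $1.8\times10^{-4}$ and at least five-fold below
the high-rate regime.

What the simulator does *not* emulate — and therefore what passing tests
do not show about real data: mutational hotspots and rate heterogeneity
(the control region's hypervariable sites), length heteroplasmy around
16189, heteroplasmy in general, selection, and realistic base composition
(the synthetic reference is uniform-random).  It is a correctness harness
for the pipeline's arithmetic, not a demographic inference engine.

Saturation guard: configurations with $\mu L g > L/2$ are refused rather
than silently wrapped.

## Numerical and degenerate-input choices

* Variant collisions (two records touching one base of one sample) are a
  hard error listing the positions, never silently resolved.
* `N`/ambiguity columns yield no call; non-ACGT columns are ignored
  pairwise in distances.
* Classification ties are deterministic (lexicographic) and flagged.
* Sites × samples with zero variation: spectrum and diversity return
  zeros, trees return warned stars; nothing throws on merely boring data.
* Samples with zero variant rows are invisible in a profile tibble, so
  every cohort-level function accepts a `samples` roster; the pipeline
  threads the roster automatically.
* All randomness (simulator, bootstrap) flows through a mandatory seed via
  `withr::with_seed`, so no call perturbs the session RNG.

## Problem sizes used in the test suite

The suite exercises the genuine cohort scale where it matters (20 full
16,569-bp genomes for the bundled matrix; 16,569-bp simulated cohorts for
the diversity-regime and slope-recovery properties) and drops to 1.5–3 kb
synthetic genomes for round-trip and oracle checks where length is
irrelevant to the property; bootstrap tests use 100 replicates against the
500-replicate default.  These sizes are the package's own choice of
smallest-faithful instances for each property.

## Known limitations

* No heteroplasmy, quality scores, or de novo assembly: input is aligned
  consensus sequence or called profiles.
* No pairwise alignment: sequences must already be in the reference frame
  (gaps allowed).
* The novelty screen is as good as its catalog snapshot; counts of "novel"
  variants are database-version dependent by nature, so the package treats
  them as reportable output, not as a reproducible constant — the bundled
  catalog is explicitly synthetic.
* Frequency tables do not test for differences between groups; no
  neutrality statistics (Tajima's D etc.) are computed.
* tRNA genes are not annotated in the bundled rCRS map (no analysed site
  falls in one); a user-supplied gene table can add them.
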