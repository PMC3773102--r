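---
title: "SSR diversity, Nei distance and heterosis in mixed-ploidy rice panels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR diversity, Nei distance and heterosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrheterosis)
```

This vignette explains the statistical model behind each stage of the
package, the conventions adopted where the field's practice is ambiguous, and
what the simulation-based tests do and do not demonstrate.

## The data model

An SSR genotype in this package is a *set* of allele labels, not a counted
genotype. On a silver-stained gel a diploid inbred cultivar shows one or two
bands; an autotetraploid derivative shows one to four. Crucially, a
tetraploid showing two bands may be AAAB, AABB or ABBB — the dosage is
unobservable. The `genotype_panel` container therefore stores raw label sets
per individual and locus (cells like `"A/B/C"`, missing calls as `.`),
together with ploidy, subspecies subgroup, and an explicit `pair_id` linking
each diploid cultivar to its tetraploid derivative. Pairing is metadata, not
a naming convention, though `infer_pairs_from_suffix()` can fill it from
`-2x`/`-4x` suffixes. Phenotypes live in a long-format `trait_table`
(entity, trait, replicate, value) so unbalanced replicate counts are
unremarkable, and a `cross_plan` records each hybrid's parents and — for
tetraploid hybrids — the diploid hybrid made from the same cultivar pair.

## Allele frequencies under dosage ambiguity

Because dosage is unknown, `allele_frequencies()` exposes two estimation
modes:

* **copy (equal-dose), the default**: each scored individual contributes
  `ploidy` copies split equally across its distinct bands. A tetraploid
  showing A,B contributes two copies of each. On fixed inbred lines — the
  realistic state of rice cultivars — this is exact.
* **presence**: one count per band per individual, the classical
  band-presence scoring for polyploids.

The two modes coincide whenever all individuals at a locus carry the same
number of distinct bands (in particular on fully fixed lines); they diverge
on mixtures of homozygous and heterozygous calls, which is why both are kept
and reported in the spectrum's `mode` field. Frequencies are renormalized
over the individuals actually scored, so missing data reduce the effective
sample size rather than bias the spectrum; loci with fewer than two scored
individuals are flagged rather than dropped, and all-missing loci are dropped
with a logged warning.

## Diversity statistics

From a spectrum *p₁…p_k* the package computes Na, Ae = 1/Σp²,
He = 1 − Σp², I = −Σ p ln p, and PIC. Two PIC variants exist in the
literature under one name. The simplified form 1 − Σp² is identical to He;
the Botstein form subtracts the chance that a cross of two identically
heterozygous parents is uninformative:

PIC = 1 − Σp² − Σ_{i<j} 2 p_i² p_j².

Published per-locus tables in this domain are only internally consistent
under the Botstein form (an equifrequent biallelic locus printed as He 0.500
with PIC 0.375, and He 0.455 with PIC ≈ 0.351), so Botstein is the default
and `pic_simple()` is retained for literal reproduction of the simplified
formula. For an equifrequent k-allele locus the closed form is
PIC = 1 − 1/k − (k−1)/k³, which the test suite checks against a brute-force
double loop.

He uses the plain 1 − Σp² by default; the small-sample correction
2n/(2n−1) is available via `unbiased = TRUE` but changes nothing at the
third decimal for panels of 40 cultivars (0.04875 vs 0.04937 for the 39:1
locus — both print as 0.049).

Report output rounds to 3 decimals, half away from zero, matching how such
tables are conventionally printed; note `round_half_away(0.3514875, 3)` is
0.351 while double-rounded displays sometimes print 0.352. Column summaries
use the sample standard deviation (n−1), reported as missing for a
single-locus table.

## Nei distance between cultivars

Genetic distance uses Nei's (1972) standard distance
D = −ln(J̄xy/√(J̄x·J̄y)), the default output of the classical population
genetics packages, with the 1978 unbiased variant as an option. Because the
analysis clusters 80 individual cultivars rather than populations, each
inbred line is treated as a (near-)fixed population whose "frequencies" are
its own equal-dose copy proportions. Loci missing in either member of a pair
are excluded pairwise. A pair sharing no allele at any locus has identity 0
and infinite distance; it is replaced by a configurable cap (default 10 —
far beyond any observed Nei D) with a warning, so fully disjoint pairs
remain clusterable. Identities marginally above 1 from floating-point are
clamped to 1, making D exactly 0 for identical spectra. Dice and Jaccard
band-sharing distances (1 − similarity) are provided as an alternative
backend for comparison with similarity-based cluster analyses.

## Neighbor joining

`neighbor_joining()` implements the canonical agglomeration: at each step
with r taxa it joins the pair minimizing Q(i,j) = (r−2)d(i,j) − R_i − R_j
and assigns branch lengths by the two-point formulas. Two numerical
conventions matter:

* **Ties** (exactly equal Q, common in capped or symmetric matrices) are
  broken by the lexicographically smallest pair of cluster representative
  labels, so runs are bit-reproducible and label-permutation equivariant.
* **Negative branch-length estimates**, which NJ can produce on non-additive
  input, are clamped to 0 with the negative amount transferred to the
  adjacent branch (the usual convention); pre-clamp values are kept in the
  `clamped` attribute.

On exactly additive matrices the algorithm recovers the generating tree's
topology and branch lengths to numerical precision; the tests verify this on
random 5–10-taxon trees via cophenetic reconstruction and cross-check the
topology against an independent NJ implementation on tie-free random
matrices. Trees serialize to Newick with fixed decimal precision and
single-quoted labels where needed; bootstrap support and figure rendering are
out of scope.

## Heterosis

All heterosis statistics operate on entity means over replicates, the
standard practice for trial summaries:

* heterobeltiosis HB = 100·(F1 − BP)/BP, with BP the better parent. "Better"
  defaults to the larger mean for every trait — consistent with uniformly
  negative published heterobeltiosis for traits like seed set where hybrids
  underperform — and can be overridden per trait, in which case the sign is
  flipped so positive always means superiority in the preferred direction.
* mid-parent heterosis MP = 100·(F1 − (P1+P2)/2)/((P1+P2)/2), the standard
  companion; HB ≤ MP whenever larger is better.
* competitive heterosis CH = 100·(F1₄ₓ − F1₂ₓ)/F1₂ₓ, defined exactly for
  the tetraploid crosses with a declared diploid counterpart.

Zero denominators yield missing values with warnings rather than errors, so
one degenerate trait cannot abort a batch. Per-cross significance uses a
two-sided Welch t on replicates at α = 0.05 — the published tables do not
name their test, so this default is documented, not asserted as the
original choice. The trait-variation table reports per-group mean, range and
CV plus a paired two-sided t across `pair_id`-matched cultivars (df =
n_pairs − 1); identical groups give t = 0, p = 1, and zero-variance nonzero
differences give a missing t with a warning. Summary percentages print at 2
decimals.

## Association

Pearson correlation with p from t = r√((n−2)/(1−r²)) on n−2 df, two-sided,
stars at 0.05/0.01, pairwise-complete deletion with n reported per cell; OLS
regression with R² = r². No multiple-testing correction is applied by
default, matching the single-table reporting convention; a
Benjamini–Hochberg option exists but is off.

## The simulator: what it emulates and what it does not

`simulate_panel()` generates the study conditions: 40 cultivar pairs, 99
loci, allele counts drawn from {2:0.42, 3:0.36, 4:0.14, 5:0.08} (the
empirical spectrum of such panels), two subspecies subgroups. Subgroup
frequencies are Dirichlet draws around a flat-Dirichlet ancestral vector
with concentration (1−F)/F — a Balding–Nichols-style divergence model. The
divergence default F = 0.35 was chosen once as a strongly structured
inter-subspecific panel: at that level the NJ tree places the two subgroups
on disjoint subtrees in essentially every replicate, the published
clustering pattern. Cultivars are fully inbred fixed lines by default
(residual heterozygosity configurable); tetraploids are copy-then-mutate
derivatives, gaining or losing one allele within the locus pool at rate
μ = 0.08 per locus, so a minority of pairs remain genotypically identical to
their parents while most diverge — the qualitative split seen in published
trees. Missing calls are added at rate 0.01. Rejection sampling keeps every
drawn allele observed among the diploids, so the realized allele-count
spectrum matches the configured one (verified by χ² at 5,000 loci).

`simulate_diallel_traits()` uses the minimal structure able to express both
"distance predicts yield heterosis" and "distance predicts nothing": parent
means uniform over published per-trait ranges (tetraploid means scaled by
the published 4×/2× group ratios), and

F1 = MP · (1 + (dominance + β·D)/100) + noise,

so dominance and β·D are exactly the expected mid-parent heterosis
percentages. Defaults: 3 replicates (an RCBD-style trial), replicate CV 5%,
modest dominance (10% for yield, 2–5% elsewhere), and coupling on yield only
with β₄ₓ = 40 %/D, β₂ₓ = 0 — the published qualitative contrast.

The simulator does **not** model coalescent SSR mutation, linkage,
segregation within crosses, genotype-by-environment interaction, or any
mechanistic link from genotypes to traits beyond the β·D term. Passing tests
therefore demonstrate that the statistical machinery is correct and that the
pipeline recovers known generating parameters — not that real rice data
would show these effects.

## The recovery study and problem sizes

`gd_coupling_replicate()` is the package's parameter-recovery unit: a
16-pair, 48-locus panel, a 4×7 incomplete diallel (28 crosses per ploidy,
the published trial's shape), β₄ₓ = 60, β₂ₓ = 0, and parent yield means
narrowed to an elite 2.5–3.5 t band. The narrowing is a design decision with
a power rationale: heterobeltiosis divides by the better parent, so wide
parent spreads inject variance that has nothing to do with the coupling
being estimated; a recovery study holds nuisance variation down. Under these
conditions the tetraploid GD–yield correlation is significantly positive in
≥95 of 100 seeds while the diploid group stays at the nominal 5% false
positive rate — the "predictive in 4×, null in 2×" contrast. The
acceptance-level checks use 100 seeds of this unit, 100 random additive
matrices for NJ, 1,000 random spectra for the PIC oracle and 1,000 null
replicates for p-value uniformity; these sizes give the property checks
clear resolution while keeping a full run in minutes on one CPU.

## Degenerate inputs and numerical conventions

* Frequencies are strictly positive and renormalized to sum 1; monomorphic
  spectra give He = I = PIC = 0, Ae = 1 exactly.
* Identity clamping (I ≤ 1), distance capping (I = 0), NJ length clamping
  and negative-zero normalization in Newick output are all explicit, logged
  where they fire.
* `round_half_away()` implements decimal display rounding (ties away from
  zero) rather than banker's rounding.
* Paired t with fewer than 2 complete pairs, correlations with fewer than 3
  complete pairs or zero variance, and regressions on constant x all return
  missing values with warnings.
* Seeds: every simulation config carries its own seed; pipeline stages derive
  trait seeds from the run seed with large offsets so panel and trait RNG
  streams never overlap across neighbouring seeds.

## Known limitations

Tetraploid dosage is never inferred, only conventionally weighted; the Nei
"individual as population" device is standard for cultivar clustering but
makes D sensitive to residual heterozygosity; published per-locus tables
contain a handful of internally impossible cells (He inconsistent with the
printed allele count) that no computation can reproduce and that are
excluded from validation; and the published tree topology itself cannot be
reproduced without the undeposited raw genotypes — only its structural
properties (two subspecies groups, a minority of undiverged pairs) are
checked on simulated data.
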