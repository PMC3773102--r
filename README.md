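# ssrheterosis

SSR (microsatellite) diversity and heterosis analysis for mixed-ploidy rice
panels: diploid cultivars alongside their colchicine-derived autotetraploid
lines.

Breeding programs that explore autotetraploid rice face a recurring chain of
questions: how much marker diversity does chromosome doubling add, how do the
doubled lines relate to their diploid parents, how strong is the hybrid vigor
of inter-subspecific (indica × japonica) crosses at each ploidy level, and
does the parents' marker-based genetic distance predict that vigor? This
package implements the full analysis chain as reusable, tested R functions,
together with a seeded simulator of paired 2×/4× panels and diallel trials so
every stage can be validated without field data.

## What it computes

**Per-locus diversity** from allele frequencies *p₁…p_k* (with explicit
dosage conventions for tetraploid band patterns, where allele dosage is
unobservable):

- observed (*Na*) and effective (*Ae* = 1/Σp²) allele numbers,
- expected heterozygosity *He* = 1 − Σp² (unbiased 2n/(2n−1) correction
  optional),
- Shannon information index *I* = −Σ p ln p,
- polymorphism information content, both the Botstein form
  PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j² (default) and the simplified 1 − Σp².

**Genetic distance and clustering**: Nei (1972) standard distance
D = −ln[J̄xy/√(J̄x·J̄y)] between cultivars (each inbred line's frequencies are
its own equal-dose copy proportions) or pooled groups, with the 1978 unbiased
variant and Dice/Jaccard band-sharing distances as options; neighbor-joining
(Saitou & Nei Q-criterion, deterministic lexicographic tie-breaks) with
Newick export.

**Heterosis** for diallel hybrid trials, on entity means over replicates:

- heterobeltiosis HB = 100·(F1 − BP)/BP against the better parent
  (direction-aware),
- mid-parent heterosis MP = 100·(F1 − MP)/MP,
- competitive heterosis CH = 100·(F1₄ₓ − F1₂ₓ)/F1₂ₓ of each tetraploid hybrid
  over the diploid hybrid from the same cultivar pair,
- per-trait min/max/mean and +/− count summaries, paired-t trait-variation
  tables across 2×/4× cultivar pairs, and Welch-t per-cross significance.

**Association**: Pearson correlation (two-sided p, 0.05/0.01 stars) of
parental genetic distance with per-cross heterobeltiosis, yield–trait
heterobeltiosis correlations, and OLS regression of yield heterobeltiosis on
genetic distance.

## Worked example

```r
library(ssrheterosis)

# allele frequencies under the equal-dose convention: a tetraploid showing
# bands A/B/C contributes 4/3 copies of each
pan <- genotype_panel(
  markers     = data.frame(name = "RM1"),
  individuals = data.frame(id = c("cv1", "cv2", "cv3"), ploidy = c(2, 2, 4)),
  calls       = matrix(c("A", "A/B", "A/B/C"), ncol = 1)
)
allele_frequencies(pan, "RM1")
#> allele_spectrum [RM1] (copy, n=3): A=0.542 B=0.292 C=0.167

# a full simulated study: 12 cultivar pairs, 20 loci, 2x3 diallel
fx <- end_to_end_fixture(seed = 42)
div <- diversity_table(split_by_ploidy(fx$panel)$tetraploid)
round_half_away(attr(div, "summary"), 3)
#>           Na Ae_eff    He     I PIC_botstein PIC_simple
#> mean   3.300  2.545 0.577 1.003        0.514      0.577
#> st_dev 1.031  0.644 0.130 0.290        0.132      0.130
#> min    2.000  1.385 0.278 0.451        0.239      0.278
#> max    5.000  3.470 0.712 1.397        0.665      0.712

tree <- neighbor_joining(fx$dm)
is_monophyletic_split(tree, with(fx$panel$individuals, id[subgroup == "indica"]))
#> [1] TRUE     # the two subspecies occupy disjoint subtrees

# genetic-distance coupling: one replicate of the recovery study
# (28 crosses per ploidy; yield heterosis coupled to Nei D in the 4x group)
gd_coupling_replicate(seed = 42)
#>   ploidy  n          r            p
#> 1      2 28 0.05944139 7.638266e-01
#> 2      4 28 0.79622008 4.040673e-07
```

The summary block reads as a POPGENE-style per-locus report footer: simulated
tetraploids average 3.3 alleles per locus with mean gene diversity 0.577. The
last table shows the package's central contrast: with distance-coupled yield
heterosis present only in the tetraploid crosses, the correlation is strong
and highly significant there (r ≈ 0.80) and indistinguishable from noise in
the diploids.

A command-line front end with verbs `simulate`, `diversity`, `tree`,
`heterosis`, `associate`, `all` is installed at
`inst/scripts/ssr_pipeline.R`; each stage writes delimited reports, Newick /
PHYLIP files and a JSON provenance record into the output directory.

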