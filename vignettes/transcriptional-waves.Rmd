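---
title: "Classifying transcriptional waves in stimulus-response time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional waves in stimulus-response time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`txwaves` analyses short bulk RNA-seq time courses of stimulated cells: an
untreated baseline at 0 h and two post-stimulus timepoints (3 h and 8 h by
default), each measured in biological replicates, for one or two stimulus
conditions. The motivating system is primary microglia stimulated with the
purinergic receptor agonist bzATP, alone or combined with LPS, where the
first stimulus drives a short-lived transcriptional wave and the
combination a sustained one. This vignette explains the model, its
assumptions, the tunable parameters, the design decisions that were
genuinely open, and what the synthetic validation does and does not show.

## The nine-trend model

Let `f1` and `f2` be a gene's log2 fold changes at 3 h and 8 h versus the
untreated baseline, computed from group means of TMM-normalized expression
with a pseudocount. With a threshold τ:

* 3 h label: Up if `f1 > τ`, Down if `f1 < −τ`, Same otherwise;
* 8 h label: Up if `f2 − f1 > τ`, Down if `f2 − f1 < −τ`, Same otherwise;
* the combined trend is the pair, one of nine classes.

Three decisions here were open and are worth recording:

* **τ = 0.5 on log2.** The threshold could also be read as "a 50% change",
  i.e. the band 0.67–1.5-fold, whose log2 half-width is ≈ 0.585. We treat
  the tabulated 0.5 as normative and expose `tau` as a parameter; the two
  choices differ only for fold changes between 1.41× and 1.50×.
* **Boundaries map to Same.** Mixed strict/non-strict inequalities across
  the nine rows of a threshold table would leave ties ambiguous or doubly
  assigned; a uniform ties-to-Same policy makes the classifier a total
  function, which the tests verify by exhaustive grid enumeration against
  an independently coded rule table.
* **The late trend is relative to 3 h.** Whether the 8 h fold change is
  defined against the baseline (then differenced with `f1`) or directly
  against the 3 h group is immaterial: the shared baseline cancels, so
  `f2 − f1` *is* the 8 h-vs-3 h log fold change. The equality is exact even
  with the pseudocount, because the same pseudocount enters both group
  means; the suite asserts label-level identity of the two readings on
  random inputs.

Filtered gene lists follow from the classification: monotonic DE genes
(Up–Up / Down–Down with `q < 0.05` and mean TMM > 10), and slow-kinetic
genes (Same at 3 h, Up/Down at 8 h at a strict late `q < 1e-10`). The
significance filter for the monotonic lists defaults to both timepoints
(`both_timepoints = TRUE`), since a gene claimed to change monotonically
should be significant at each step; the single-timepoint reading is
available as a flag.

## Normalization

TMM scaling factors are implemented from their published definition rather
than called from a library (the installed edgeR implementation serves as an
independent oracle in the test suite). For sample *s* against reference
*r*, genes with a zero in either sample are dropped, per-gene log
count-fraction ratios `M` and abundances `A` are doubly trimmed (30% of
each tail by `M`, 5% by `A`), and the factor is the inverse-variance
weighted mean of the surviving `M` values, with the delta-method binomial
variance `(N−y)/(Ny)` per sample as the precision weight's reciprocal.
Factors are rescaled to geometric mean 1, and expression is reported as
TMM-scaled counts per million — the "TMM" unit in which all thresholds
(>10 for expression, >25 for abundant ncRNAs) are stated. The reference is
the sample whose upper-quartile count fraction is closest to the mean of
that quantity, ties to the first sample.

Two practical notes. The trimming is by rank with ties broken by position,
so the factor is deterministic; and because the precision weights depend on
absolute counts (not count fractions), rescaling a sample's counts perturbs
its factor at the 1e-4–1e-3 level on realistic data — exact scale
invariance holds only when the log ratios are constant.

The expression filter keeps genes whose mean TMM across the union of the
baseline and contrasted groups strictly exceeds `min_tmm = 10`. Which
groups enter that average is exposed as an argument because the averaging
set for the second contrast is a convention.

## Differential expression

The DE engine is a conditioned negative-binomial exact test, a deliberate,
documented simplification of a GLM machinery: counts are first equalized to
the geometric mean of the effective library sizes (library size × TMM
factor; deterministic scaling, rounded), after which per-group sums are
exchangeable NB variables under the null. Conditioning on the total, the
two-sided p-value sums the probabilities of all splits whose conditional
probability does not exceed the observed one (probability ordering — the
standard deterministic two-sided convention for discrete tests), capped at
1. At φ = 0 the conditional law is exactly binomial, which the tests
exploit as a Poisson-limit oracle via direct enumeration. Probabilities are
accumulated in log space; for totals above 2×10⁵ the enumeration is
restricted to ±50 conditional standard deviations, outside of which the
omitted mass is below 1e-15.

The common dispersion φ is a method-of-moments average: per gene and
replicate group, `(variance − mean)/mean²`; the finite values are averaged
and the average floored at 0. Averaging only positive per-gene estimates
would bias φ upward by an order of magnitude at 3 replicates (the per-gene
estimator is extremely noisy, roughly symmetric around the truth), so the
floor applies to the average, not the terms. Counts are depth-equalized
before estimation when effective library sizes are supplied — otherwise
depth spread between replicates masquerades as biological overdispersion
and makes the test conservative. No tagwise shrinkage is attempted: a
common φ is the desk-scale choice, and the planted-data validation shows
it calibrates the test adequately (null type-I error within 0.05 ± 0.02 at
2,000 genes).

Benjamini–Hochberg q-values are computed by the step-up rule directly
(`q(i) = min over j ≥ i of p(j)·m/j`), cross-checked against
`stats::p.adjust` in the tests. Fold changes use a pseudocount of 0.25 TMM
on both group means so logs stay finite for unexpressed groups.

## Gene sets, biotypes, PCA

Gene-set share profiles treat the set's summed group-mean TMM as 100% and
report each member's percentage — shares are scale-invariant and sum to
100 by construction, which the suite asserts. Biotype partitioning reads
`gene_type` from gene-level GTF records with a dialect-tolerant attribute
parser (quotes and trailing semicolons optional, attribute order free;
errors cite the offending line number); "coding" is the `protein_coding`
biotype exactly and every other biotype counts as non-coding. The
abundant-DE-ncRNA filter takes non-coding genes with mean TMM > 25
(strict), at least 2-fold late change (non-strict, so exactly 2-fold
qualifies), and late q < 0.05. PCA operates on `log2(TMM + 1)` with genes
centered but not scaled — unit-variance scaling would let thousands of
near-noise flat genes drown the planted signal; the transform is a
documented choice, not a claim about the only reasonable one.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` draws NB counts for the five-group design (baseline
0 h; two stimulated conditions at 3 h and 8 h) with 3 biological replicates
per group. Per-gene baseline means are log-uniform over `10^0.5`–`10^3.5`
and rescaled so a sample's expected library size is 3×10⁶; per-sample
depths vary with CV 0.2 (or explicit library sizes). Planted classes
follow the nine trends with effect size 2.0 log2 for every wave class
(e.g. a transient wave is ×4 at 3 h, back to baseline at 8 h), 90% of genes
flat — choices that mirror a strong acute stimulation experiment in which
most of the transcriptome is unchanged. Dispersion defaults to φ = 0.05, a
typical bulk RNA-seq value; the class and biotype allocations are exact
(largest-remainder rounding) so tests can assert counts, and effects are
applied identically in both stimulated conditions so either contrast
recovers them.

What the simulator deliberately does not model: gene-to-gene dispersion
variation (a single common φ), correlated genes, batch or library-prep
effects, gene-length bias, and any coupling between biotype and expression
level or responsiveness. Passing the planted-recovery tests therefore shows
that the pipeline correctly inverts its own generative assumptions at
realistic noise levels — it does not certify performance on real data,
where tagwise dispersion and correlation structure would loosen the
recovery rates.

A quantitative consequence of the NB noise floor is worth stating: with 3
replicates and φ = 0.05, the group-mean log2-FC standard deviation cannot
fall below ≈ 0.26 no matter how abundant the gene, so even an all-flat
simulation classifies only ~86–90% of genes Same–Same at τ = 0.5; the
fraction exceeds 95% once φ ≤ 0.01. The validation suite encodes both
regimes explicitly rather than pretending the threshold has no noise cost.

## Problem sizes and numerical conventions

The shipped validation runs at sizes chosen to finish in seconds while
leaving Monte-Carlo margins well clear of their bounds: 2,000-gene
simulations for recovery and test calibration, 5,000 genes for
normalization accuracy under a 3× depth spread, 10,000 genes in the
study-scale acceptance run. Degenerate inputs have defined behavior
throughout: all-zero samples, empty gene sets, annotation-free GTFs and
mismatched gene universes raise errors naming the offending object;
identical samples yield zero PCA variance with a warning rather than an
error; the reference sample against itself has factor exactly 1. All
tie-breaks (trend boundaries, trimming ranks, induction ranking) are
deterministic, and pipeline outputs are byte-reproducible given identical
inputs.

## Limitations

Two post-baseline timepoints only; no GLM covariates or batch terms; a
common dispersion; no gene-length normalization (within-gene comparisons
across samples are unaffected, cross-gene abundance shares inherit the
length bias of count-based units); trend assignment is hard, with no
uncertainty propagated from the fold-change estimates into the labels.
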