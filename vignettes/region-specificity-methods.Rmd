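---
title: "Methods: permutation-calibrated region-specificity of duplicated genes"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: permutation-calibrated region-specificity of duplicated genes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regiotau)
```

This vignette is the package's own account of its statistical machinery:
the models and rules each stage implements, the tunable parameters and why
their defaults are what they are, the numerical edge cases, and what the
synthetic-data validation does and does not establish about real data.

## The data model

The pipeline consumes a gene × sample RPKM matrix over 13 sampled CNS
regions, a sample table with covariates (sequencing platform, age, sex and
the first three genotype principal components), and a per-gene duplication
annotation (paralog/singleton status; WGD / SSD / WGD-SSD / unannotated
category; for SSDs an age class ySSD / wSSD / oSSD relative to the two
vertebrate whole-genome duplications; family membership with the family's
*total* size; phyletic age; genomic coordinates).

Preprocessing mirrors the standard treatment of such atlases:

1. **Filtering.** Genes with null variance across all samples are dropped,
   then genes whose mean RPKM is below `low_expr_rpkm` (default 0.1) in
   *every* one of the 13 regions. The two filters commute; they are applied
   in this order only so the removal log is reproducible.
2. **Transform.** `log2(RPKM + 1)`, elementwise.
3. **Covariate adjustment.** Per gene, OLS of the transformed values on
   platform, age, sex and PC1–3; the output is residuals *plus the fitted
   intercept*, so between-gene mean differences survive adjustment.
   Categorical covariates use treatment coding with the most frequent level
   as reference: residuals are coding-invariant, and keeping the fitted
   intercept preserves each gene's grand structure regardless of the
   reference choice. Single-level covariates are dropped (they are the
   intercept); a genuinely collinear design is an error naming the columns,
   not a silent pseudo-inverse. Adjusted values may be negative; they are
   passed through unchanged — clipping is the specificity stage's decision
   (below).
4. **Region merge.** The 13 sampled regions collapse onto 7 territories by
   a fixed map (two cerebellar samplings, three cortical, three striatal,
   amygdala with hippocampus; hypothalamus, spinal cord and substantia
   nigra map to themselves). A territory mean is the *unweighted average of
   its constituent region means*, not the pooled sample mean: sub-regions
   are sampled unequally, and pooling would weight a territory's profile by
   sampling depth rather than anatomy. Merging exists so that a gene shared
   between anatomically overlapping sub-regions is not spuriously
   penalised as "non-specific".

## Tau and its permutation calibration

For per-territory means \(x_1,\dots,x_n\) (here \(n = 7\)),

\[
\tau \;=\; \frac{\sum_{i=1}^n\bigl(1 - x_i/\max_j x_j\bigr)}{n - 1},
\]

which is 0 for a flat profile and 1 for expression confined to one
territory, and is invariant to positive rescaling of the profile.

**Clipping rule.** Tau requires non-negative means, but covariate
adjustment can push means below zero. Negative means are clipped to 0
before the ratio: this preserves the \([0,1]\) bounds and the
max-normalisation semantics, and treats "adjusted below zero" as "not
expressed", which is the only reading consistent with the index. A profile
that is all-zero after clipping has no defined specificity; such genes get
`NA` and are excluded from specificity calls.

**The null.** Within one organ the Tau distribution is unimodal, so no
fixed cutoff separates specific from broad genes. The null is built by
permuting the sample-to-region labels: labels are shuffled at the
13-region level and the merge map applied afterwards, so each permuted
territory mean is fed by the same unequal sub-region group sizes as the
observed one. Per permutation, territory means and Tau are recomputed for
every gene.

**Pooled versus per-gene.** By default all permuted scores are pooled
(`n_permutations × n_genes` values), giving p-value resolution of order
\(10^{-5}\)–\(10^{-7}\) instead of `1/n_permutations`; with a shared null,
p-values are monotone in Tau, which forces the called set to be exactly
\(\{\tau \ge \tau_{\text{threshold}}\}\) — the threshold is read off as
the smallest Tau among called genes. The pooled null assumes genes are
exchangeable against a common reference distribution; genes with unusually
noisy profiles borrow the tail of quieter genes, which is the price of the
added resolution. A per-gene mode (`pooled = FALSE`) is available when
that assumption is unacceptable; it is calibrated per gene but cannot
resolve p below `1/n_permutations`.

**Estimator.** The empirical p-value uses the add-one estimator
\((k+1)/(N+1)\), where \(k\) counts null scores *strictly* greater than
the observed Tau (ties count as not-higher). The add-one form cannot
return 0 and is the standard positively biased permutation estimator; the
plain proportion \(k/N\) is available (`estimator = "plain"`) and differs
negligibly at pooled-null sizes. Benjamini–Hochberg correction across
genes at `fdr_alpha` (default 0.01) defines the called set.

**Region assignment.** A called gene is assigned to its maximal-mean
territory. Exact ties are resolved to the lexicographically first territory
name with a warning — deterministic, and visible rather than silent.

**Summaries.** `bin_by_expression()` bins each gene's maximal territory
mean into unit `log2(RPKM+1)` bins with a final open bin at 127 RPKM
(`log2(128) = 7`), reporting per bin and gene class the count and percent
called specific; `tau_by_phyletic_age()` summarises Tau quartiles per
phyletic-age value.

## Enrichment statistics

All enrichments are 2×2 contingency tests: tested group inside a stated
universe × property yes/no. The test is chi-squared *without* continuity
correction — at the gene-universe sizes involved (thousands) the
correction is immaterial, and omitting it matches the reconstructed
published values — falling back to Fisher's exact test when any expected
cell count is below 5, the standard reading of "when the chi-squared test
cannot be applied". The odds ratio is the unconditional cross-product
ratio \(ad/bc\) (infinite with a warning when \(bc = 0\)), not the
conditional MLE: the cross-product form is what the reconstructed
published ratios follow. Bonferroni thresholds are `alpha / n_tests`.
`enrichment_test()` takes an explicit exclusion set so analyses that
remove the non-co-expressed members of homogeneous families can state that
rule as data rather than code. Linear models of Tau on maximal expression
plus duplication indicators (`tau_linear_model()`) come in the three
standard designs — paralog status over all genes, duplication type within
paralogs, age class within SSDs — and are ordinary `lm` fits with
`tidy()`/`glance()` access.

## Co-expression modules and family homogeneity

Modules are detected on the expressed paralogs only: Pearson correlation
across all samples, unsigned soft-threshold adjacency
\(a_{ij} = |r_{ij}|^\beta\) (signed mode by flag; unsigned is the
conventional default and shared regulation within families is the target
signal), topological overlap similarity

\[
t_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
               {\min(k_i,k_j) + 1 - a_{ij}},
\]

average-linkage clustering of \(1 - t\), a coarse cut at `cut_height`
(default 0.99), and a deep-split refinement: each unit of `deep_split`
(0–4, default 4) doubles how far the refinement cut descends below the
coarse height, i.e. the effective height is
\(1 - (1-\text{cut\_height})\cdot 2^{\text{deep\_split}}\) (0.84 at the
defaults, floored at 0.3). Loose aggregates held together only by weak
average similarity dissolve into their tight cores; coherent clusters
survive. Clusters below `min_module_size` (default 2 — families of two
must be able to form a module) become label 0, the unassigned pool.
Labels are canonicalised by decreasing module size so the assignment is
invariant to gene input order. `soft_power = "auto"` picks the smallest
\(\beta \in \{1..20\}\) whose connectivity distribution reaches a
scale-free fit \(R^2 \ge 0.8\), falling back to 6; on strongly planted
synthetic structure the fit can be reached at low powers that separate
modules less sharply, so the validation suite pins \(\beta = 6\), the
conventional unsigned choice.

A family is **homogeneous** when strictly more than `homogeneity_fraction`
(default 0.60) of its *total* members — unexpressed members count in the
denominator — share one module. The main module is the modal non-zero
label; a modal tie is conservatively heterogeneous. Members of homogeneous
families outside the main module form an exclusion set for downstream
tests. Significance of the homogeneous-family count is assessed by
permuting module labels across paralogs (preserving the label multiset)
and re-applying the rule, with p = (#{null ≥ observed} + 1)/(B + 1): the
permutation is over labels, not over re-inferred networks, which tests
exactly whether family membership predicts module co-membership given the
module structure.

## Families and pairs

A family is **region-specific** when strictly more than
`majority_fraction` (default 0.5) of its *expressed* members are called
specific to the same territory (modal ties fail). The expressed-member
denominator parallels the treatment of expressed paralogs elsewhere; the
fraction is a config parameter because reasonable variants exist.

Pair analyses use only **reciprocal** pairs: listed in both orientations
with the same duplication category; orientation conflicts are dropped with
a message. Distance classes partition coordinate-complete pairs: different
chromosomes → inter-chromosomal; same chromosome closer than `tandem_bp`
(default 1 Mb) → tandem; otherwise intra-chromosomal. Distance is
start-to-start: strand-free and deterministic; any missing coordinate
yields class `unknown`, excluded from distance tests. Shared-specificity
summaries report, per category, the fraction of both-specific pairs
assigned to the same territory, always alongside the raw counts so small
denominators are visible.

## The synthetic-data generator

`simulate_expression()` emulates the study conditions: 13 named regions at
97 samples each by default (within the real cohort's 63–125 range), the
real per-class gene counts (16,427 genes: 6,092 singletons, 5,114 WGD,
1,192 ySSD, 1,260 wSSD, 1,267 oSSD, 966 WGD-SSD, 536 unannotated),
families built within class with 47% of size 2 and a decaying tail, and
per-class planted region-specific fractions equal to the observed rates
(13.9%–28.6%).

Abundance is log-normal on the RPKM scale: on log2 units, value =
per-gene baseline + planted elevation + family factor + covariate terms +
N(0, `noise_sd`), and RPKM = \(2^{\text{value}} - 1\) floored at 0, so
counts are never needed (differential expression is out of scope).
Choices that matter:

- **Baselines** are class-specific (ySSDs lowest, 1.8 log2 units ≈ 2.5
  RPKM; other classes 2.5–3.2, peaking near the 7–15 RPKM range), with
  per-gene dispersion 0.75 and a left truncation at 1.0 log2 units. The
  truncation encodes that the generator models the *post-filter* expressed
  universe: a near-zero gene has an essentially undefined profile whose
  permuted Tau sits at the extreme tail, and a population of such genes
  makes the pooled null uninformative for everything else. Dispersion and
  truncation were fixed once, to give the validation suite working power
  at the documented effect size, and are not biological estimates.
- **Planted specificity** elevates the gene's target territory by
  `specificity_effect` (fold on RPKM; default 4). Effects are planted at
  the 7-territory level so the 13→7 merge can never split a planted
  signal. No effect-size scale is available to copy, so the default is a
  test-power choice, stated as such.
- **Family structure.** Each family draws one target territory; a planted
  specific member uses the family target with a per-class probability
  (0.59 for ySSD down to 0.31 for WGD), which produces the class gradient
  in pair-level shared specificity. A fraction of families
  (`frac_homogeneous_families`, default 0.05) is homogeneous: members
  share one latent per-*sample* factor (SD 1.0). Deliberately per-sample,
  not per-region: co-expression then leaves region labels exchangeable, so
  a zero-planting simulation is an exact null for the permutation
  calibration while still carrying detectable module structure.
- **Covariates** act through a common per-sample term with per-gene
  susceptibility (mean 1, SD 0.5), so adjustment has something real to
  remove; tandem placement of size-2 families follows per-class
  probabilities (0.60 ySSD down to 0.02 WGD), emulating the
  young-duplicates-in-tandem gradient.

What the generator does *not* emulate: read-level noise, mappability
artifacts of segmental duplications (which bias real quantification of
the youngest SSDs), RNA-integrity effects, region-specific cell-type
composition, or correlated covariates. Passing the validation suite
therefore shows the *machinery* is correct and calibrated under the
stated model — not that real data satisfy that model.

## Problem sizes and numerical conventions in the validation suite

The suite validates at sizes chosen to exercise each property quickly:
the shared fixture is 600 genes × 130 samples; the null-calibration run
uses the full 16,427-gene class profile at 13 × 20 samples with 200
permutations; planted-signal recovery uses ~3,000 genes at 13 × 30
samples and effect 4; family-homogeneity recovery uses 480 paralogs at
13 × 8 samples with noise SD 0.15 and 30% homogeneous families; the
homogeneity permutation bound uses 1,000 permutations. Oracle checks are
exhaustive where feasible (all ≤ 5-territory integer-grid profiles for
Tau) and brute-force elsewhere (≤ 10-gene TOM instances, tolerance
1e-12). All simulation tests fix their seeds; pipeline outputs are
byte-identical under a fixed `rng_seed`, which is stamped, with the
configuration hash, into every output header.

## Known limitations

- The pooled null trades per-gene calibration for resolution (discussed
  above); heteroskedastic gene populations make it liberal for the
  noisiest genes. Both modes ship; pooled is the default interpretation.
- The deep-split refinement is a transparent two-height rule, not a full
  adaptive branch-cutting algorithm; very heterogeneous module tightness
  within one dataset may favour the latter.
- `soft_power = "auto"` optimises scale-free fit, which is not the same
  objective as module separability; pin the power when comparability
  matters.
- Family homogeneity uses total family size in the denominator, so a
  family with many unexpressed members can never be homogeneous — a
  faithful but conservative rule.
- The enrichment odds ratio is the sample cross-product ratio; no
  confidence intervals are reported.
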