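# regiotau

Intra-organ region-specificity analysis of duplicated gene expression.

Bulk RNA-seq atlases of the human central nervous system (CNS) sample many
territories of a single organ. `regiotau` asks which genes are expressed
specifically in one territory rather than broadly across all of them, and
whether gene duplication — whole-genome duplication (WGD) versus small-scale
duplication (SSD), and the age of the SSD event — shapes that specificity.
It is aimed at computational biologists studying paralog evolution and
regional transcriptome specialisation who have (i) a gene × sample
abundance matrix in RPKM, (ii) a sample-to-region table with technical and
biological covariates, and (iii) a paralog/family annotation.

## The statistic at the core

For each gene, expression is averaged per region and summarised by the Tau
specificity index over the *n* = 7 merged CNS territories:

    tau = sum_i (1 - x_i / max_j x_j) / (n - 1)

Tau is 0 for a uniform profile and 1 for expression confined to a single
territory. Because no universal Tau cutoff separates "specific" from
"broad" within one organ, the threshold is calibrated empirically: the
sample-to-region labels are permuted (1000 times by default), Tau is
recomputed for every gene, and all permuted scores are pooled into a null
distribution. Each gene's empirical p-value is the proportion of null
scores above its observed Tau; Benjamini–Hochberg correction across genes
at FDR < 0.01 defines the specific set, and the smallest Tau among specific
genes is the operative threshold. Each specific gene is assigned to the
territory where it is most expressed.

Around that core the package provides:

- preprocessing exactly as the analysis expects it: variance and
  0.1-RPKM-per-region filters, log2(RPKM + 1), per-gene OLS adjustment for
  platform, age, sex and three genotype PCs (residuals keep the fitted
  intercept), and the fixed 13-to-7 region merge;
- duplication-category enrichment statistics (chi-squared or Fisher 2×2
  tests, cross-product odds ratios, Bonferroni thresholds) plus rank tests
  and linear models of Tau on expression and duplication status;
- co-expression module detection (soft-power adjacency, topological
  overlap, average-linkage clustering with a deep-split refinement) and a
  classification of gene families into homogeneous / heterogeneous with a
  label-permutation significance test;
- family-level region-specificity calls and paralog-pair analyses
  (reciprocal pair construction, tandem / intra- / inter-chromosomal
  distance classes, shared-territory fractions);
- a synthetic GTEx-like data generator with full ground truth, so every
  classifier in the package can be validated end to end.

## Worked example

```r
library(regiotau)

fx  <- fixture_small(1)            # 600 genes x 130 samples, known truth
adj <- fx$expression |>
  filter_genes(fx$samples) |>      # variance + 0.1 RPKM region filter
  log_transform() |>
  adjust_covariates(fx$samples)

calls <- tau_specificity(adj, fx$samples, n_permutations = 200, seed = 5)
calls
#> <tau_calls> 600 genes, 42 region-specific (7.0%) at FDR < 0.01
#>   tau threshold: 0.4371 (null size 120000)

head(tidy(calls)[order(-tidy(calls)$tau), ], 3)
#>   gene_id   tau empirical_p q_value assigned_region
#> 1 G00593  0.751  0.00000833 0.00125 cerebellum
#> 2 G00394  0.722  0.00000833 0.00125 cerebellum
#> 3 G00434  0.673  0.00000833 0.00125 spinal cord
```

42 of 600 genes clear the permutation-calibrated threshold (Tau ≥ 0.437);
the top genes are confined to the cerebellum and spinal cord, the
territories with the most distinctive transcriptomes. The enrichment
battery then contrasts duplication categories:

```r
standard_enrichment(calls, fx$annotation)
#>   tested_group reference_group pct_tested      p_value odds_ratio test_used
#> 1 paralogs     protein coding        8.75 0.0175            2.64  chi_squared
#> 2 WGD          paralogs              2.14 0.000600          0.156 chi_squared
#> 3 SSD          paralogs             13.6  0.000132          5.53  chi_squared
#> 4 ySSD         paralogs             20.8  0.0000000216      7.11  chi_squared
#> 5 ySSD         SSD                  20.8  0.000656          5     chi_squared
#> 6 oSSD         SSD                   0    0.00139           0     chi_squared
#> 7 wSSD         WGD+wSSD             10    0.0308            5.07  fisher
```

On this simulated dataset the planted structure is recovered: SSDs — and
young SSDs most of all — are enriched in region-specific genes (odds
ratios above 1), while WGD and old-SSD genes are depleted (below 1), the
same sign pattern the method is designed to detect. `run_pipeline()`
chains all stages on input files and writes six provenance-stamped TSV
tables; `autoplot(calls)`, `plot_expression_bins()` and friends draw the
standard figures.

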