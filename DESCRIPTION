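Package: regiotau
Title: Region-Specificity of Duplicated Gene Expression Within an Organ
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intra-organ region-specific expression of
    duplicated genes from bulk RNA-seq abundance matrices. Implements the
    Tau specificity index with a permutation-calibrated, FDR-controlled
    region-specificity threshold; duplication-category enrichment
    statistics (chi-squared / Fisher contingency tests with odds ratios
    and Bonferroni control); topological-overlap co-expression module
    detection and classification of gene families into homogeneous and
    heterogeneous co-expression classes with a permutation significance
    test; family-level region-specificity calls and paralog-pair genomic
    distance analyses; and a synthetic data generator that emulates
    GTEx-like brain expression data with known ground truth for every
    downstream classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
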