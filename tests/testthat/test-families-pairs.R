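fake_calls <- function(genes, specific, region) {
  tibble::tibble(
    gene_id = genes,
    tau = ifelse(specific, 0.8, 0.2),
    max_region_mean = 3,
    empirical_p = ifelse(specific, 1e-4, 0.6),
    q_value = ifelse(specific, 1e-3, 0.8),
    is_region_specific = specific,
    assigned_region = ifelse(specific, region, NA_character_)
  )
}

test_that("family region-specificity follows the strict majority rule", {
  ann <- dplyr::bind_rows(
    ann_row(c("a1", "a2"), family_id = "fa", family_total_size = 2L),
    ann_row(c("b1", "b2", "b3", "b4"), family_id = "fb",
            family_total_size = 4L),
    ann_row(c("c1", "c2", "c3"), family_id = "fc", family_total_size = 3L)
  )
  calls <- fake_calls(
    ann$gene_id,
    specific = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    region = c("cerebellum", "cerebellum",
               "cerebellum", "cerebellum", NA, NA,
               "cortex", "cerebellum", "hypothalamus"))
  fams <- classify_family_specificity(calls, ann)
  st <- setNames(fams$status, fams$family_id)
  # both members specific to cerebellum: specific family
  expect_identical(unname(st["fa"]), "region_specific")
  expect_identical(fams$major_region[fams$family_id == "fa"], "cerebellum")
  # 2 of 4 expressed share a region: 2 > 0.5 * 4 is false
  expect_identical(unname(st["fb"]), "not_region_specific")
  # three different regions: modal tie
  expect_identical(unname(st["fc"]), "not_region_specific")

  # member order is irrelevant
  perm <- sample(nrow(ann))
  fams_p <- classify_family_specificity(calls[perm, ], ann[perm, ])
  expect_equal(dplyr::arrange(fams_p, family_id),
               dplyr::arrange(fams, family_id))
})

test_that("pair construction enforces reciprocity and category agreement", {
  raw <- tibble::tibble(
    gene_a = c("a", "b", "c", "d", "e", "g", "h"),
    gene_b = c("b", "a", "d", "c", "f", "h", "g"),
    dup_category = c("SSD", "SSD", "SSD", "WGD", "SSD", "WGD", "WGD")
  )
  expect_message(pairs <- build_pairs(raw), "conflicting")
  # (a,b) reciprocal same category: kept; (c,d) category conflict: dropped;
  # (e,f) single orientation: dropped; (g,h) kept
  expect_identical(sort(pairs$gene_a), c("a", "g"))
  expect_true(all(pairs$reciprocal))
  expect_true(all(pairs$gene_a < pairs$gene_b))
})

test_that("pair distance classes partition coordinate-complete pairs", {
  ann <- dplyr::bind_rows(
    ann_row("p1", chrom = "chr1", start = 1e6),
    ann_row("p2", chrom = "chr1", start = 1.5e6),
    ann_row("p3", chrom = "chr1", start = 0),
    ann_row("p4", chrom = "chr1", start = 5e6),
    ann_row("p5", chrom = "chr1", start = 100),
    ann_row("p6", chrom = "chr2", start = 100),
    ann_row("p7", chrom = "chr3", start = NA)
  )
  pairs <- tibble::tibble(
    gene_a = c("p1", "p3", "p5", "p5"),
    gene_b = c("p2", "p4", "p6", "p7"),
    dup_category = "SSD", reciprocal = TRUE
  )
  out <- classify_distance(pairs, ann)
  expect_identical(out$distance_class,
                   c("tandem", "intra_chromosomal", "inter_chromosomal",
                     "unknown"))
  expect_equal(out$distance_bp[1], 5e5)
  known <- out$distance_class != "unknown"
  expect_true(all(known ==
                    (out$distance_class %in%
                       c("tandem", "intra_chromosomal",
                         "inter_chromosomal"))))
})

test_that("shared pair specificity counts same-region pairs per category", {
  pairs <- tibble::tibble(
    gene_a = c("y1", "y3", "w1"),
    gene_b = c("y2", "y4", "w2"),
    dup_category = c("SSD", "SSD", "WGD"), reciprocal = TRUE
  )
  calls <- fake_calls(
    c("y1", "y2", "y3", "y4", "w1", "w2"),
    specific = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    region = c("cortex", "cortex", "cerebellum", NA,
               "cortex", "spinal cord"))
  out <- pair_shared_specificity(pairs, calls)
  ssd <- out[out$dup_category == "SSD", ]
  # the (y3,y4) pair has a non-specific member: excluded from denominator
  expect_equal(ssd$n_both_specific, 1)
  expect_equal(ssd$frac_same_region, 1)
  wgd <- out[out$dup_category == "WGD", ]
  expect_equal(wgd$n_both_specific, 1)
  expect_equal(wgd$frac_same_region, 0)
})

test_that("planted tandem ySSD pairs share territories more than WGD pairs", {
  ng <- c(singleton = 200, WGD = 700, ySSD = 500, wSSD = 60, oSSD = 60,
          WGD_SSD = 0, unannotated = 0)
  fx <- simulate_expression(sim_spec(
    samples_per_region = 30, n_genes = ng,
    frac_region_specific = c(singleton = 0.15, WGD = 0.3, ySSD = 0.5,
                             wSSD = 0.2, oSSD = 0.2, WGD_SSD = 0.2,
                             unannotated = 0.2),
    rng_seed = 51))
  adj <- suppressMessages(filter_genes(fx$expression, fx$samples)) |>
    log_transform() |>
    adjust_covariates(fx$samples)
  calls <- tau_specificity(adj, fx$samples, n_permutations = 60, seed = 52)
  pair_raw <- fx$truth$pairs |>
    dplyr::select("gene_a", "gene_b", "dup_category")
  pairs <- build_pairs(dplyr::bind_rows(
    pair_raw,
    dplyr::select(pair_raw, gene_a = "gene_b", gene_b = "gene_a",
                  "dup_category")))
  ann_class <- fx$annotation
  yssd_pairs <- pairs[pairs$gene_a %in%
                        ann_class$gene_id[ann_class$ssd_age == "ySSD"], ]
  wgd_pairs <- pairs[pairs$dup_category == "WGD", ]
  sh_y <- pair_shared_specificity(yssd_pairs, calls)
  sh_w <- pair_shared_specificity(wgd_pairs, calls)
  expect_gt(sh_y$n_both_specific, 5)
  expect_gt(sh_w$n_both_specific, 5)
  expect_gt(sh_y$frac_same_region, sh_w$frac_same_region)

  # distance classes on simulated coordinates agree with the planted truth
  dist <- classify_distance(pairs, fx$annotation)
  truth_pairs <- fx$truth$pairs
  joined <- dplyr::inner_join(dist, truth_pairs,
                              by = c("gene_a", "gene_b"),
                              suffix = c("", "_truth"))
  expect_gt(nrow(joined), 50)
  expect_identical(joined$distance_class, joined$distance_class_truth)
  # ySSD pairs are planted in tandem far more often than WGD pairs
  tandem_rate <- joined |>
    dplyr::group_by(dup_category) |>
    dplyr::summarise(rate = mean(distance_class == "tandem"))
  expect_gt(tandem_rate$rate[tandem_rate$dup_category == "SSD"],
            tandem_rate$rate[tandem_rate$dup_category == "WGD"])
})
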