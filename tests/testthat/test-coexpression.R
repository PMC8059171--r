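# hand-built expression block: `k` genes driven by latent profile `z` with
# additive noise
block <- function(k, z, noise, prefix, seed) {
  set.seed(seed)
  out <- t(vapply(seq_len(k), function(i) z + rnorm(length(z), 0, noise),
                  numeric(length(z))))
  rownames(out) <- sprintf("%s%02d", prefix, seq_len(k))
  out
}

test_that("TOM matches the brute-force oracle and its structural bounds", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    cc <- matrix(runif(n * n, -1, 1), n)
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    a <- abs(cc)^6
    diag(a) <- 0
    tom <- tom_similarity(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("planted two-block structure is recovered exactly at low noise", {
  ns <- 60
  set.seed(41)
  z1 <- rnorm(ns)
  z2 <- rnorm(ns)
  vals <- rbind(block(6, z1, 0.01, "a", 1), block(5, z2, 0.01, "b", 2))
  colnames(vals) <- sprintf("s%02d", seq_len(ns))
  m <- expr_matrix(vals, "adjusted")
  mods <- infer_modules(m, soft_power = 6)
  expect_identical(max(mods$module), 2L)
  # canonical labels: module 1 is the larger block
  expect_true(all(mods$module[grepl("^a", mods$gene_id)] == 1L))
  expect_true(all(mods$module[grepl("^b", mods$gene_id)] == 2L))

  # gene input order changes nothing after canonical relabelling
  perm <- sample(nrow(vals))
  mods_p <- infer_modules(expr_matrix(vals[perm, ], "adjusted"),
                          soft_power = 6)
  expect_identical(mods_p$module[match(mods$gene_id, mods_p$gene_id)],
                   mods$module)
})

test_that("uncorrelated genes stay unassigned and constant genes error", {
  set.seed(42)
  vals <- matrix(rnorm(30 * 80), 30, 80,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%02d", 1:80)))
  mods <- infer_modules(expr_matrix(vals, "adjusted"), soft_power = 6)
  expect_true(all(mods$module == 0L))

  vals[3, ] <- 2
  expect_error(infer_modules(expr_matrix(vals, "adjusted"), soft_power = 6),
               "g03")
})

test_that("family homogeneity applies the strict total-size rule", {
  ann <- dplyr::bind_rows(
    # size-5 family, 3 members in one module: 3/5 = 0.60, NOT homogeneous
    ann_row(sprintf("f5_%d", 1:5), family_id = "f5", family_total_size = 5L),
    # size-2 family fully co-modular: homogeneous
    ann_row(sprintf("f2_%d", 1:2), family_id = "f2", family_total_size = 2L),
    # size-3 family with only 2 expressed, both co-modular: 2/3 > 0.60
    ann_row(sprintf("f3_%d", 1:2), family_id = "f3", family_total_size = 3L),
    # modal tie -> heterogeneous
    ann_row(sprintf("ft_%d", 1:4), family_id = "ft", family_total_size = 4L)
  )
  mods <- tibble::tibble(
    gene_id = ann$gene_id,
    module = c(7L, 7L, 7L, 1L, 2L,  3L, 3L,  4L, 4L,  5L, 5L, 6L, 6L)
  )
  fams <- classify_families(mods, ann)
  st <- setNames(fams$status, fams$family_id)
  expect_identical(unname(st["f5"]), "heterogeneous") # 0.60 not > 0.60
  expect_identical(unname(st["f2"]), "homogeneous")
  expect_identical(unname(st["f3"]), "homogeneous")
  expect_identical(unname(st["ft"]), "heterogeneous")
  expect_equal(fams$fraction[fams$family_id == "f3"], 2 / 3)
  # the two f5 members outside the main module are not excluded (family is
  # heterogeneous); excluded set only collects homogeneous-family outliers
  expect_identical(excluded_genes(fams), character(0))

  # an unassigned (0) member of a homogeneous family lands in the excluded set
  ann2 <- ann_row(sprintf("h_%d", 1:3), family_id = "h",
                  family_total_size = 3L)
  mods2 <- tibble::tibble(gene_id = ann2$gene_id, module = c(9L, 9L, 0L))
  fams2 <- classify_families(mods2, ann2)
  expect_identical(fams2$status, "homogeneous")
  expect_identical(excluded_genes(fams2), "h_3")

  # bookkeeping: every family with an expressed member is classified
  fx <- small_fixture()
  mods_fx <- infer_modules(small_adjusted()[
    rownames(small_adjusted()) %in%
      fx$annotation$gene_id[fx$annotation$status == "paralog"], ],
    soft_power = 6)
  fams_fx <- classify_families(mods_fx, fx$annotation)
  n_fam_expressed <- dplyr::n_distinct(
    fx$annotation$family_id[!is.na(fx$annotation$family_id) &
                              fx$annotation$gene_id %in% mods_fx$gene_id])
  expect_identical(nrow(fams_fx), n_fam_expressed)
  expect_true(all(fams_fx$n_in_main <= fams_fx$n_expressed))
  expect_true(all(fams_fx$n_expressed <= fams_fx$n_total))
})

test_that("planted homogeneous families are recovered at low noise", {
  ng <- c(singleton = 0, WGD = 200, ySSD = 100, wSSD = 60, oSSD = 60,
          WGD_SSD = 40, unannotated = 20)
  fx <- simulate_expression(sim_spec(
    samples_per_region = 8, n_genes = ng,
    frac_homogeneous_families = 0.3, noise_sd = 0.15, rng_seed = 21))
  adj <- suppressMessages(filter_genes(fx$expression, fx$samples)) |>
    log_transform() |>
    adjust_covariates(fx$samples)
  mods <- infer_modules(adj, soft_power = 6)
  fams <- suppressMessages(classify_families(mods, fx$annotation))
  truth <- fx$truth$families[match(fams$family_id,
                                   fx$truth$families$family_id), ]
  called <- fams$status == "homogeneous"
  expect_gte(mean(called[truth$is_homogeneous]), 0.9)   # sensitivity
  expect_gte(mean(truth$is_homogeneous[called]), 0.9)   # precision
})

test_that("the homogeneous-family count permutation test is calibrated", {
  ng <- c(singleton = 0, WGD = 200, ySSD = 100, wSSD = 60, oSSD = 60,
          WGD_SSD = 40, unannotated = 20)
  fx <- simulate_expression(sim_spec(
    samples_per_region = 8, n_genes = ng,
    frac_homogeneous_families = 0.3, noise_sd = 0.15, rng_seed = 21))
  adj <- suppressMessages(filter_genes(fx$expression, fx$samples)) |>
    log_transform() |>
    adjust_covariates(fx$samples)
  mods <- infer_modules(adj, soft_power = 6)
  ht <- homogeneity_permutation_test(mods, fx$annotation,
                                     n_permutations = 300, seed = 3)
  # strong planted structure: the observed count clears every null count
  expect_true(all(ht$null_counts < ht$observed))
  expect_lte(ht$empirical_p, 1 / 301)

  # with labels already shuffled there is no signal: p is not extreme
  set.seed(77)
  shuffled <- mods
  shuffled$module <- sample(shuffled$module)
  ht0 <- homogeneity_permutation_test(shuffled, fx$annotation,
                                      n_permutations = 200, seed = 4)
  expect_gt(ht0$empirical_p, 0.05)

  # estimator support at a single permutation
  ht1 <- homogeneity_permutation_test(mods, fx$annotation,
                                      n_permutations = 1, seed = 5)
  expect_true(ht1$empirical_p %in% c(1 / 2, 1))
})
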