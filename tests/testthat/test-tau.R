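test_that("tau matches hand-computed values and its defining invariants", {
  expect_equal(compute_tau(c(1, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(compute_tau(rep(3, 7)), 0)
  expect_equal(compute_tau(c(2, 1, 1, 1, 1, 1, 1)), 0.5)
  expect_true(is.na(compute_tau(c(0, 0, 0))))
  expect_true(is.na(compute_tau(c(-1, -2, 0)))) # clipped to all-zero
  expect_error(compute_tau(5), "at least 2")

  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:9, 1)
    x <- runif(n, 0, 10)
    tau <- compute_tau(x)
    expect_gte(tau, 0)
    expect_lte(tau, 1)
    # scale invariance
    expect_equal(compute_tau(3.7 * x), tau)
    # monotone in the largest mean
    x2 <- x
    x2[which.max(x)] <- max(x) * 2
    expect_gte(compute_tau(x2), tau - 1e-12)
  }
})

test_that("tau equals the brute-force oracle on an exhaustive integer grid", {
  for (n in 2:5) {
    grid <- as.matrix(expand.grid(rep(list(0:4), n)))
    grid <- grid[rowSums(grid) > 0, , drop = FALSE]
    got <- apply(grid, 1L, compute_tau)
    want <- apply(grid, 1L, brute_tau)
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("permutation null is reproducible and matches exchangeable data", {
  fx <- small_fixture()
  adj <- small_adjusted()
  n1 <- permutation_null(adj, fx$samples, n_permutations = 1, seed = 3)
  n2 <- permutation_null(adj, fx$samples, n_permutations = 1, seed = 3)
  expect_identical(n1$pooled_scores, n2$pooled_scores)

  # under label-exchangeable data the observed tau distribution matches the
  # pooled null (small two-sample KS statistic)
  ng <- c(singleton = 400, WGD = 200, ySSD = 100, wSSD = 0, oSSD = 0,
          WGD_SSD = 0, unannotated = 0)
  null_sim <- simulate_expression(sim_spec(
    samples_per_region = 12, n_genes = ng,
    frac_region_specific = c(singleton = 0, WGD = 0, ySSD = 0, wSSD = 0,
                             oSSD = 0, WGD_SSD = 0, unannotated = 0),
    frac_homogeneous_families = 0, rng_seed = 17))
  m0 <- suppressMessages(filter_genes(null_sim$expression, null_sim$samples)) |>
    log_transform() |>
    adjust_covariates(null_sim$samples)
  taus0 <- tau_table(m0, null_sim$samples)
  null0 <- permutation_null(m0, null_sim$samples, n_permutations = 40,
                            seed = 18)
  ks <- suppressWarnings(
    stats::ks.test(taus0$tau, sample(null0$pooled_scores, 5000)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("specificity calls are threshold-consistent and match planted truth", {
  calls <- small_calls()
  res <- calls$results
  # p monotone in tau under a pooled null: the specific set is exactly the
  # tau >= threshold set
  expect_true(is.finite(calls$tau_threshold))
  expect_identical(res$is_region_specific %in% TRUE,
                   !is.na(res$tau) & res$tau >= calls$tau_threshold)

  # boundary of the add-one estimator
  top <- which.max(res$tau)
  n_pool <- calls$n_null
  if (res$tau[top] > max(calls$null$pooled_scores)) {
    expect_equal(res$empirical_p[top], 1 / (n_pool + 1))
  }
  # tau = 0 can never be specific
  lows <- res$empirical_p[!is.na(res$tau) & res$tau == 0]
  if (length(lows) > 0) expect_true(all(lows > 0.99))

  truth <- truth_for(res$gene_id)
  called <- res$is_region_specific
  expect_gt(mean(res$tau[truth$is_region_specific], na.rm = TRUE),
            median(res$tau[!truth$is_region_specific], na.rm = TRUE))
  # recovered planted genes land on their planted territory
  ok <- called & truth$is_region_specific
  expect_gt(sum(ok), 10)
  expect_gte(mean(res$assigned_region[ok] == truth$target_region[ok]), 0.95)
  # the most specific planted genes clear the null's extreme tail
  null999 <- unname(quantile(calls$null$pooled_scores, 0.999))
  planted_tau <- res$tau[truth$is_region_specific]
  expect_gt(mean(planted_tau > null999, na.rm = TRUE), 0.2)
  expect_true(all(sort(planted_tau, decreasing = TRUE)[1:10] > null999))
})

test_that("per-gene null mode and tie-broken region assignment behave", {
  fx <- small_fixture()
  adj <- small_adjusted()
  nullpg <- permutation_null(adj, fx$samples, n_permutations = 60,
                             seed = 9, pooled = FALSE)
  expect_identical(dim(nullpg$gene_scores), c(nrow(adj), 60L))
  taus <- tau_table(adj, fx$samples)
  r7 <- region_means(adj, fx$samples, "r7")
  calls_pg <- suppressWarnings(
    call_specific(taus, nullpg, r7, fdr_alpha = 0.05, per_gene = TRUE))
  expect_true(all(calls_pg$results$empirical_p >= 1 / 61, na.rm = TRUE))

  # an exact tie between two territories resolves lexicographically
  smp <- toy_samples(1)
  vals <- matrix(rep(c(rep(1, 12), 5), length.out = 2 * 13), 2, 13,
                 byrow = TRUE, dimnames = list(c("gA", "gB"),
                                               smp$sample_id))
  # gA: 5 in amygdala, hippocampus and substantia nigra -> the merged
  # amygdala-hippocampus territory ties with substantia nigra at 5
  vals["gA", ] <- 1
  vals["gA", smp$region_13 %in%
         c("amygdala", "hippocampus", "substantia nigra")] <- 5
  m <- expr_matrix(vals, "adjusted")
  r7t <- region_means(m, smp, "r7")
  best <- colnames(r7t)[r7t["gA", ] == max(r7t["gA", ])]
  expect_length(best, 2L)
  fake_null <- structure(list(pooled_scores = seq(0, 0.2, by = 0.01),
                              n_permutations = 1L, n_genes = 2L,
                              pooled = TRUE, seed = 1L),
                         class = "tau_null")
  tt <- tau_table(m, smp)
  expect_warning(cl <- call_specific(tt, fake_null, r7t, fdr_alpha = 0.5),
                 "tied")
  expect_identical(cl$results$assigned_region[1], sort(best)[1])
})

test_that("expression bins follow the unit-log2 rule with a 127 RPKM cap", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    tau = c(0.9, 0.2, 0.8, 0.5),
    max_region_mean = c(log2(0.5 + 1), 1.2, log2(127 + 1), 7.8),
    empirical_p = 0.5, q_value = 0.5,
    is_region_specific = c(TRUE, FALSE, TRUE, FALSE),
    assigned_region = NA_character_
  )
  classes <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                            class = c("x", "x", "y", "y"))
  bins <- bin_by_expression(res, classes)
  expect_identical(bins$bin[bins$class == "x"], c("[0,1)", "[1,2)"))
  # 127 RPKM is exactly log2(128) = 7: it belongs to the open-ended bin
  expect_identical(sort(unique(bins$bin[bins$class == "y"])), "[7,Inf)")
  expect_equal(bins$pct_specific[bins$bin == "[7,Inf)"], 50)
})

test_that("phyletic-age summaries group, summarise and drop NA ages", {
  calls <- small_calls()
  fx <- small_fixture()
  expect_message(ages <- tau_by_phyletic_age(calls, fx$annotation),
                 "without phyletic age")
  expect_true(all(c("phyletic_age", "n", "q25", "median", "q75")
                  %in% names(ages)))
  expect_true(all(diff(ages$phyletic_age) > 0))
  # young SSDs are planted more specific than old ones: their median tau
  # should exceed the oSSD-range median
  ann <- fx$annotation
  res <- calls$results
  young <- res$tau[res$gene_id %in% ann$gene_id[ann$ssd_age == "ySSD"]]
  old <- res$tau[res$gene_id %in% ann$gene_id[ann$ssd_age == "oSSD"]]
  expect_gt(median(young, na.rm = TRUE), median(old, na.rm = TRUE))
})
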