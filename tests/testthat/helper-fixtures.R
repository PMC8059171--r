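# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the vectorised implementations.

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

small_fixture <- function() cached("fx", fixture_small(1))

small_adjusted <- function() cached("adj", {
  fx <- small_fixture()
  suppressMessages(filter_genes(fx$expression, fx$samples)) |>
    log_transform() |>
    adjust_covariates(fx$samples)
})

small_calls <- function() cached("calls", {
  fx <- small_fixture()
  suppressWarnings(
    tau_specificity(small_adjusted(), fx$samples,
                    n_permutations = 200, seed = 5)
  )
})

# truth rows aligned to a gene id vector
truth_for <- function(gene_ids) {
  fx <- small_fixture()
  fx$truth$genes[match(gene_ids, fx$truth$genes$gene_id), ]
}

# independent specificity-index oracle: explicit elementwise loop
brute_tau <- function(x) {
  x <- vapply(x, function(v) if (v < 0) 0 else v, numeric(1))
  mx <- x[1]
  for (v in x) if (v > mx) mx <- v
  if (mx == 0) return(NA_real_)
  acc <- 0
  for (v in x) acc <- acc + (1 - v / mx)
  acc / (length(x) - 1)
}

# independent topological-overlap oracle: triple loop over the definition
brute_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      num <- a[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# a tiny valid annotation row builder
ann_row <- function(gene_id = "g1", status = "paralog",
                    dup_category = "SSD", ssd_age = "ySSD",
                    family_id = "fam1", family_total_size = 2L,
                    phyletic_age = 0.12, chrom = "chr1", start = 1000) {
  tibble::tibble(
    gene_id = gene_id, status = status, dup_category = dup_category,
    ssd_age = ssd_age, family_id = family_id,
    family_total_size = family_total_size, phyletic_age = phyletic_age,
    chrom = chrom, start = start
  )
}

# minimal sample table for hand-built matrices: n samples per region over
# the first `n_regions` of the 13 region names
toy_samples <- function(n_per_region = 2, regions = regions_13(),
                        seed = 99) {
  set.seed(seed)
  ns <- n_per_region * length(regions)
  tibble::tibble(
    sample_id = sprintf("t%03d", seq_len(ns)),
    region_13 = rep(regions, each = n_per_region),
    platform = rep_len(c("A", "B"), ns),
    age = seq(30, 60, length.out = ns),
    sex = rep_len(c("F", "F", "M", "M"), ns),
    pc1 = rnorm(ns), pc2 = rnorm(ns), pc3 = rnorm(ns)
  )
}
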