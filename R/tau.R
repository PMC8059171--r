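#' Tau specificity index
#'
#' For a vector of per-region mean expression values \eqn{x_1..x_n},
#' \deqn{\tau = \frac{\sum_i (1 - \hat x_i)}{n - 1}, \quad
#'       \hat x_i = x_i / \max_i x_i.}
#' Tau is 0 for a perfectly uniform profile and 1 for expression confined to
#' a single region. Negative inputs (possible after covariate adjustment)
#' are clipped to zero before normalisation, preserving the `[0, 1]` bounds.
#' An all-zero profile has no defined specificity and returns `NA`.
#'
#' @param x Numeric vector of `n >= 2` per-region means.
#' @return Tau in `[0, 1]`, or `NA_real_` for an all-zero (after clipping)
#'   profile.
#' @export
#' @examples
#' compute_tau(c(1, 0, 0, 0, 0, 0, 0)) # 1: perfectly specific
#' compute_tau(rep(3, 7))              # 0: uniform
#' compute_tau(c(2, 1, 1, 1, 1, 1, 1)) # 0.5
compute_tau <- function(x) {
  if (length(x) < 2L) abort("compute_tau() needs at least 2 region means")
  x <- pmax(x, 0)
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

# row-wise Tau over a gene x region mean matrix; NA rows where max == 0
.tau_rows <- function(means) {
  means <- pmax(means, 0)
  mx <- do.call(pmax, as.data.frame(means))
  tau <- rowSums(1 - means / ifelse(mx == 0, NA_real_, mx)) / (ncol(means) - 1L)
  tau
}

#' Observed Tau scores with the reference expression value
#'
#' Computes, per gene, Tau over the 7-territory means together with the
#' maximal territory mean (the Fig.-style reference expression value used
#' for expression binning).
#'
#' @param m An `expr_matrix`, normally in the `adjusted` state.
#' @param samples Sample attribute table.
#' @return A tibble with `gene_id`, `tau`, `max_region_mean`.
#' @export
tau_table <- function(m, samples) {
  r7 <- region_means(m, samples, level = "r7")
  tibble::tibble(
    gene_id = rownames(r7),
    tau = unname(.tau_rows(r7)),
    max_region_mean = unname(do.call(pmax, as.data.frame(pmax(r7, 0))))
  )
}

#' Permutation null distribution of Tau
#'
#' Shuffles the sample-to-region labels at the 13-region level (the merge
#' map is then applied, so the null respects the unequal sub-region sample
#' sizes feeding each merged mean), recomputes the 7-territory means and Tau
#' for every gene, and pools the scores. The pooled null (permutations x
#' genes values) gives p-value resolution far finer than 1/n_permutations;
#' per-gene nulls are retained when `pooled = FALSE`.
#'
#' @param m An `expr_matrix`, normally `adjusted`.
#' @param samples Sample attribute table.
#' @param n_permutations Number of label permutations (published setting 1000).
#' @param seed Integer RNG seed.
#' @param pooled Pool permuted scores across genes (default) or keep a
#'   per-gene score matrix.
#' @return A `tau_null` object: `pooled_scores` (sorted), `n_permutations`,
#'   `n_genes`, and (when `pooled = FALSE`) `gene_scores`, a genes x
#'   permutations matrix.
#' @export
permutation_null <- function(m, samples, n_permutations = 1000, seed = 1L,
                             pooled = TRUE) {
  stopifnot(n_permutations >= 1)
  samples <- .match_samples(m, samples)
  v <- unclass(m)
  ind <- .indicator_13(samples$region_13)
  w7 <- .merge_weights(colnames(ind))
  ns <- nrow(ind)
  set.seed(seed)
  scores <- matrix(NA_real_, nrow(v), n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(ns)
    scores[, b] <- .tau_rows((v %*% ind[perm, , drop = FALSE]) %*% w7)
  }
  out <- list(
    n_permutations = as.integer(n_permutations),
    n_genes = nrow(v),
    seed = as.integer(seed),
    pooled = pooled
  )
  if (pooled) {
    out$pooled_scores <- sort(as.vector(scores[!is.na(scores)]))
  } else {
    rownames(scores) <- rownames(v)
    out$gene_scores <- scores
    out$pooled_scores <- sort(as.vector(scores[!is.na(scores)]))
  }
  structure(out, class = "tau_null")
}

#' @export
print.tau_null <- function(x, ...) {
  cat(sprintf("<tau_null> %d permutations x %d genes (%s)\n",
              x$n_permutations, x$n_genes,
              if (x$pooled) "pooled" else "per-gene"))
  qs <- quantile(x$pooled_scores, c(.5, .95, .99, .999))
  cat("  null quantiles:",
      paste(sprintf("%s=%.3f", names(qs), qs), collapse = " "), "\n")
  invisible(x)
}

#' Call region-specific genes against a permutation null
#'
#' For each gene the empirical p-value is the proportion of null Tau scores
#' strictly higher than the observed score (with the add-one correction
#' `(k + 1) / (N + 1)` by default; `estimator = "plain"` gives the raw
#' proportion `k / N`). P-values are Benjamini-Hochberg corrected over all
#' genes and a gene is declared region-specific when its q-value is below
#' `fdr_alpha`. Because the pooled null is shared across genes, p-values are
#' monotone in Tau and the specific set is exactly
#' `{tau >= tau_threshold}` where `tau_threshold` is the smallest Tau among
#' specific genes. Each specific gene is assigned the territory with the
#' highest mean expression (exact ties go to the lexicographically first
#' region name, with a warning).
#'
#' @param taus A tibble from [tau_table()] (columns `gene_id`, `tau`,
#'   `max_region_mean`).
#' @param null A `tau_null` from [permutation_null()].
#' @param r7_means Gene x territory mean matrix from [region_means()]
#'   (used for region assignment).
#' @param fdr_alpha q-value cutoff (published setting 0.01).
#' @param estimator `"add_one"` (default) or `"plain"`.
#' @param per_gene Use each gene's own null scores instead of the pooled
#'   null (requires a null built with `pooled = FALSE`).
#' @return A `tau_calls` object: `$results` tibble with `gene_id`, `tau`,
#'   `max_region_mean`, `empirical_p`, `q_value`, `is_region_specific`,
#'   `assigned_region`; `$tau_threshold`; `$fdr_alpha`; `$n_null`.
#' @export
call_specific <- function(taus, null, r7_means, fdr_alpha = 0.01,
                          estimator = c("add_one", "plain"),
                          per_gene = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(null, "tau_null"))
  taus <- tibble::as_tibble(taus)

  p_from_counts <- function(k, n) {
    if (estimator == "add_one") (k + 1) / (n + 1) else k / n
  }
  if (per_gene) {
    if (is.null(null$gene_scores)) {
      abort("per-gene p-values need a null built with pooled = FALSE")
    }
    gs <- null$gene_scores[match(taus$gene_id, rownames(null$gene_scores)), ,
                           drop = FALSE]
    k <- rowSums(gs > taus$tau, na.rm = TRUE)
    n_null <- rowSums(!is.na(gs))
    p <- p_from_counts(k, n_null)
  } else {
    s <- null$pooled_scores
    n_null <- length(s)
    # strictly-greater count: ties count as not-higher
    k <- n_null - findInterval(taus$tau, s)
    p <- p_from_counts(k, n_null)
  }
  p[is.na(taus$tau)] <- NA_real_
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  specific <- !is.na(q) & q < fdr_alpha

  assigned <- rep(NA_character_, nrow(taus))
  if (any(specific)) {
    rm7 <- pmax(r7_means[match(taus$gene_id, rownames(r7_means)), ,
                         drop = FALSE], 0)
    regions <- colnames(rm7)
    ord <- order(regions) # lexicographic tie-break order
    idx <- which(specific)
    n_ties <- 0L
    for (i in idx) {
      row <- rm7[i, ]
      best <- which(row == max(row))
      if (length(best) > 1L) {
        n_ties <- n_ties + 1L
        best <- best[order(match(best, ord))][1]
      }
      assigned[i] <- regions[best[1]]
    }
    if (n_ties > 0L) {
      warn(sprintf("%d specific gene(s) had tied maximal region means; lexicographically first region assigned", n_ties))
    }
  }
  tau_threshold <- if (any(specific)) min(taus$tau[specific]) else {
    warn("no genes called region-specific; tau_threshold is +Inf")
    Inf
  }
  structure(
    list(
      results = tibble::tibble(
        gene_id = taus$gene_id,
        tau = taus$tau,
        max_region_mean = taus$max_region_mean,
        empirical_p = p,
        q_value = q,
        is_region_specific = specific,
        assigned_region = assigned
      ),
      tau_threshold = tau_threshold,
      fdr_alpha = fdr_alpha,
      n_null = if (per_gene) null$n_permutations else length(null$pooled_scores),
      estimator = estimator
    ),
    class = "tau_calls"
  )
}

#' One-call region-specificity analysis
#'
#' Convenience wrapper chaining [tau_table()], [permutation_null()] and
#' [call_specific()] on an adjusted matrix.
#'
#' @inheritParams permutation_null
#' @inheritParams call_specific
#' @return A `tau_calls` object (see [call_specific()]).
#' @export
tau_specificity <- function(m, samples, n_permutations = 1000,
                            fdr_alpha = 0.01, seed = 1L, pooled = TRUE) {
  taus <- tau_table(m, samples)
  null <- permutation_null(m, samples, n_permutations = n_permutations,
                           seed = seed, pooled = pooled)
  calls <- call_specific(taus, null, region_means(m, samples, "r7"),
                         fdr_alpha = fdr_alpha, per_gene = !pooled)
  calls$null <- null
  calls
}

#' @export
print.tau_calls <- function(x, ...) {
  n <- nrow(x$results)
  ns <- sum(x$results$is_region_specific, na.rm = TRUE)
  cat(sprintf("<tau_calls> %d genes, %d region-specific (%.1f%%) at FDR < %g\n",
              n, ns, 100 * ns / n, x$fdr_alpha))
  cat(sprintf("  tau threshold: %.4g (null size %d)\n",
              x$tau_threshold, x$n_null))
  invisible(x)
}

#' @export
tidy.tau_calls <- function(x, ...) x$results

#' @export
glance.tau_calls <- function(x, ...) {
  n_genes <- nrow(x$results)
  n_specific <- sum(x$results$is_region_specific, na.rm = TRUE)
  tibble::tibble(
    n_genes = n_genes,
    n_specific = n_specific,
    pct_specific = 100 * n_specific / n_genes,
    tau_threshold = x$tau_threshold,
    fdr_alpha = x$fdr_alpha,
    n_null = x$n_null
  )
}

#' Bin genes by maximal expression and tabulate specificity
#'
#' Bins the per-gene maximal territory mean (in log2(RPKM + 1) units) into
#' unit-width bins `[0,1), [1,2), ...`; the final bin collects everything at
#' or above 127 RPKM (log2 value 7). Per bin and gene class, reports the
#' gene count and the percentage called region-specific.
#'
#' @param calls A `tau_calls` object or its `results` tibble.
#' @param classes Tibble with `gene_id` and `class` labelling each gene
#'   (e.g. singleton/WGD/ySSD/...).
#' @return A tibble with `bin`, `class`, `n_genes`, `n_specific`,
#'   `pct_specific` (`NA` when the bin-class cell is empty it is absent).
#' @export
bin_by_expression <- function(calls, classes) {
  res <- if (inherits(calls, "tau_calls")) calls$results else
    tibble::as_tibble(calls)
  top <- log2(128) # 127 RPKM -> log2(127 + 1) = 7
  res |>
    dplyr::inner_join(tibble::as_tibble(classes), by = "gene_id") |>
    dplyr::mutate(
      bin_lo = as.integer(pmin(floor(pmax(.data$max_region_mean, 0)), top)),
      bin = ifelse(.data$bin_lo >= top, "[7,Inf)",
                   sprintf("[%d,%d)", .data$bin_lo, .data$bin_lo + 1L))
    ) |>
    dplyr::group_by(.data$bin, .data$class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_specific = sum(.data$is_region_specific, na.rm = TRUE),
      pct_specific = 100 * .data$n_specific / .data$n_genes,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin, .data$class)
}

#' Tau distribution by phyletic age
#'
#' Groups paralogs by their (distinct) phyletic-age value and summarises the
#' Tau distribution in each group. Genes without a phyletic age are dropped
#' with a message.
#'
#' @param calls A `tau_calls` object or its `results` tibble.
#' @param annotation Annotation tibble with `gene_id` and `phyletic_age`.
#' @return A tibble with `phyletic_age`, `n`, `q25`, `median`, `q75`,
#'   `pct_specific`, ordered by age.
#' @export
tau_by_phyletic_age <- function(calls, annotation) {
  res <- if (inherits(calls, "tau_calls")) calls$results else
    tibble::as_tibble(calls)
  joined <- dplyr::inner_join(
    res, dplyr::select(tibble::as_tibble(annotation),
                       "gene_id", "phyletic_age"),
    by = "gene_id")
  n_drop <- sum(is.na(joined$phyletic_age))
  if (n_drop > 0) {
    inform(sprintf("tau_by_phyletic_age: %d gene(s) without phyletic age excluded", n_drop))
  }
  joined |>
    dplyr::filter(!is.na(.data$phyletic_age), !is.na(.data$tau)) |>
    dplyr::group_by(.data$phyletic_age) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = quantile(.data$tau, 0.25),
      median = median(.data$tau),
      q75 = quantile(.data$tau, 0.75),
      pct_specific = 100 * mean(.data$is_region_specific),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$phyletic_age)
}
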