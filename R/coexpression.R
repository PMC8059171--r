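#' Soft-thresholded co-expression adjacency
#'
#' Pairwise Pearson correlation of gene expression profiles across samples,
#' raised to the soft power: unsigned `|cor|^beta` (default) or signed
#' `((1 + cor) / 2)^beta`. The diagonal is set to 0 (self-adjacency is
#' excluded from connectivity and topological overlap).
#'
#' @param m An `expr_matrix` restricted to the genes of interest.
#' @param soft_power Positive soft-thresholding power.
#' @param signed Use the signed transform.
#' @return A gene x gene adjacency matrix in `[0, 1]`, zero diagonal.
#' @export
adjacency_matrix <- function(m, soft_power = 6, signed = FALSE) {
  v <- unclass(m)
  if (nrow(v) < 2L) abort("adjacency needs at least 2 genes")
  if (ncol(v) < 3L) abort("adjacency needs at least 3 samples")
  sds <- apply(v, 1L, sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene(s) in co-expression input: ",
                 paste(head(rownames(v)[sds == 0], 5), collapse = ", ")))
  }
  cc <- cor(t(v))
  a <- if (signed) ((1 + cc) / 2)^soft_power else abs(cc)^soft_power
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' For adjacency `a` with zero diagonal and connectivity `k_i = sum_u
#' a_iu`, the topological overlap between genes i and j is
#' \deqn{t_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                     {\min(k_i, k_j) + 1 - a_{ij}},}
#' with `t_ii = 1`. Two genes overlap strongly when they are directly
#' connected and share neighbours.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]`, zero diagonal.
#' @return The TOM similarity matrix, values in `[0, 1]`, unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a          # (shared)_ij = sum_u a_iu a_uj, u free of i,j
  num <- shared + a          # since diag(a) = 0 the u = i, j terms vanish
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Choose the soft power by scale-free topology fit
#'
#' For each candidate power, the connectivity distribution is binned and
#' `log10 p(k)` regressed on `log10 k`; the signed fit index is R^2 times
#' the sign of the negative slope. The smallest power reaching
#' `r2_target` is chosen; if none does, the fallback power 6 is returned
#' with a message.
#'
#' @param m An `expr_matrix`.
#' @param powers Candidate powers (default 1..20).
#' @param r2_target Signed R^2 target (default 0.8).
#' @param signed Signed adjacency.
#' @return A list: `power` (chosen), `fit` tibble with `power`,
#'   `r_squared`, `mean_k`.
#' @export
pick_soft_power <- function(m, powers = 1:20, r2_target = 0.8,
                            signed = FALSE) {
  fit <- purrr::map_dfr(powers, function(p) {
    a <- adjacency_matrix(m, soft_power = p, signed = signed)
    k <- rowSums(a)
    keep <- k > 0
    r2 <- NA_real_
    if (sum(keep) >= 10) {
      cuts <- cut(k[keep], breaks = 10)
      dk <- tapply(k[keep], cuts, mean)
      pk <- as.vector(table(cuts)) / sum(keep)
      ok <- !is.na(dk) & pk > 0
      if (sum(ok) >= 3) {
        f <- lm(log10(pk[ok]) ~ log10(dk[ok]))
        slope <- stats::coef(f)[2]
        r2 <- summary(f)$r.squared * (-sign(slope))
      }
    }
    tibble::tibble(power = p, r_squared = r2, mean_k = mean(k))
  })
  hit <- which(!is.na(fit$r_squared) & fit$r_squared >= r2_target)
  if (length(hit) > 0) {
    power <- fit$power[hit[1]]
  } else {
    inform("no candidate power reached the scale-free fit target; falling back to power 6")
    power <- 6
  }
  list(power = power, fit = fit)
}

# deep-split refinement height: each unit of deep_split doubles how far the
# refinement cut descends below the base cut height, so deep_split = 0 keeps
# the coarse partition and deep_split = 4 dissolves loosely joined clusters
# into their tight cores
.refine_height <- function(cut_height, deep_split) {
  if (deep_split == 0L) return(cut_height)
  max(1 - (1 - cut_height) * 2^deep_split, 0.3)
}

#' Detect co-expression modules
#'
#' Correlation network module detection: soft-power adjacency, topological
#' overlap similarity, average-linkage hierarchical clustering of the TOM
#' dissimilarity, a coarse cut at `cut_height`, then a deep-split
#' refinement that re-cuts each coarse cluster deeper down the dendrogram:
#' each unit of `deep_split` doubles how far the refinement height descends
#' below `cut_height` (at the defaults, from 0.99 down to 0.84), so loose
#' aggregates dissolve into their tightly co-expressed cores while genuinely
#' coherent clusters survive intact. Clusters below `min_module_size`
#' become unassigned (label 0).
#' Module labels are canonical: numbered by decreasing size, ties by first
#' member's input position, so the labelling is invariant to gene order.
#'
#' @param m An `expr_matrix` restricted to the genes to cluster (normally
#'   the expressed paralogs, adjusted scale), with no constant genes.
#' @param soft_power Soft power or `"auto"` ([pick_soft_power()]).
#' @param signed Signed adjacency.
#' @param min_module_size Smallest retained module (default 2: families of
#'   two must be able to form a module).
#' @param cut_height Static cut height on TOM dissimilarity.
#' @param deep_split Recursive split aggressiveness, 0-4.
#' @param scale_free_r2_target Target for `"auto"` power selection.
#' @return A `module_assignment` tibble: `gene_id`, `module` (positive
#'   integer, 0 = unassigned); attributes `params` and `module_sizes`.
#' @export
infer_modules <- function(m, soft_power = "auto", signed = FALSE,
                          min_module_size = 2L, cut_height = 0.99,
                          deep_split = 4L, scale_free_r2_target = 0.8) {
  if (identical(soft_power, "auto")) {
    soft_power <- pick_soft_power(m, r2_target = scale_free_r2_target,
                                  signed = signed)$power
  }
  a <- adjacency_matrix(m, soft_power = soft_power, signed = signed)
  tom <- tom_similarity(a)
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  coarse <- cutree(hc, h = cut_height)
  fine <- cutree(hc, h = .refine_height(cut_height, as.integer(deep_split)))
  # refinement splits within the coarse clusters only (fine is nested in
  # coarse on a single dendrogram, so the interaction keeps fine's ids)
  memb <- fine + max(fine) * (coarse - 1L)
  clusters <- split(seq_len(nrow(m)), memb)
  labels <- integer(nrow(m))
  keep <- clusters[vapply(clusters, length, integer(1)) >= min_module_size]
  if (length(keep) > 0) {
    sizes <- vapply(keep, length, integer(1))
    firsts <- vapply(keep, min, integer(1))
    ord <- order(-sizes, firsts)
    for (r in seq_along(ord)) labels[keep[[ord[r]]]] <- r
  }
  out <- tibble::tibble(gene_id = rownames(m), module = labels)
  attr(out, "params") <- list(soft_power = soft_power, signed = signed,
                              min_module_size = min_module_size,
                              cut_height = cut_height,
                              deep_split = deep_split)
  attr(out, "module_sizes") <- out |>
    dplyr::filter(.data$module > 0) |>
    dplyr::count(.data$module, name = "size")
  class(out) <- c("module_assignment", class(out))
  out
}

#' Classify gene families as homogeneous or heterogeneous
#'
#' A family is homogeneous when strictly more than `homogeneity_fraction`
#' (published rule: more than 60%) of its total members — unexpressed
#' members included in the denominator — share one co-expression module.
#' The main module is the modal non-zero label; a modal tie makes the
#' family heterogeneous. Members of homogeneous families outside the main
#' module form the `excluded_genes` attribute (to be removed from
#' downstream homogeneous-family tests).
#'
#' @param modules A `module_assignment` tibble (`gene_id`, `module`).
#' @param annotation Annotation tibble (`gene_id`, `family_id`,
#'   `family_total_size`).
#' @param homogeneity_fraction Strict lower bound on the in-main-module
#'   fraction (default 0.60).
#' @return A `family_homogeneity` tibble: `family_id`, `n_total`,
#'   `n_expressed`, `main_module`, `n_in_main`, `fraction`, `status`;
#'   attribute `excluded_genes` (character vector).
#' @export
classify_families <- function(modules, annotation,
                              homogeneity_fraction = 0.60) {
  ann <- tibble::as_tibble(annotation)
  mods <- tibble::as_tibble(modules)
  fam <- ann |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::inner_join(mods, by = "gene_id")
  skipped <- setdiff(unique(ann$family_id[!is.na(ann$family_id)]),
                     unique(fam$family_id))
  if (length(skipped) > 0) {
    inform(sprintf("classify_families: %d family(ies) without expressed members skipped", length(skipped)))
  }
  summarise_family <- function(df) {
    labs <- df$module[df$module > 0]
    n_total <- df$family_total_size[1]
    if (length(labs) == 0L) {
      return(tibble::tibble(main_module = NA_integer_, n_in_main = 0L,
                            modal_tie = FALSE))
    }
    tab <- tabulate(labs)
    best <- max(tab)
    tie <- sum(tab == best) > 1L
    tibble::tibble(
      main_module = if (tie) NA_integer_ else which.max(tab),
      n_in_main = if (tie) 0L else best,
      modal_tie = tie
    )
  }
  out <- fam |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(df, key) {
      cbind(
        tibble::tibble(n_total = df$family_total_size[1],
                       n_expressed = nrow(df)),
        summarise_family(df)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fraction = .data$n_in_main / .data$n_total,
      status = ifelse(!.data$modal_tie &
                        .data$fraction > homogeneity_fraction,
                      "homogeneous", "heterogeneous")
    ) |>
    dplyr::select("family_id", "n_total", "n_expressed", "main_module",
                  "n_in_main", "fraction", "status")
  hom <- out$family_id[out$status == "homogeneous"]
  excluded <- fam |>
    dplyr::inner_join(dplyr::select(out, "family_id", "main_module"),
                      by = "family_id") |>
    dplyr::filter(.data$family_id %in% hom,
                  .data$module != .data$main_module) |>
    dplyr::pull("gene_id")
  attr(out, "excluded_genes") <- excluded
  class(out) <- c("family_homogeneity", class(out))
  out
}

#' @rdname classify_families
#' @param x A `family_homogeneity` tibble.
#' @export
excluded_genes <- function(x) {
  attr(x, "excluded_genes") %||% character(0)
}

# count homogeneous families for one label assignment; fam_idx is a list of
# integer indices into `labels`, n_total the matching family sizes
.count_homogeneous <- function(labels, fam_idx, n_total, h) {
  hits <- 0L
  for (i in seq_along(fam_idx)) {
    labs <- labels[fam_idx[[i]]]
    labs <- labs[labs > 0L]
    if (length(labs) == 0L) next
    tab <- tabulate(labs)
    best <- max(tab)
    if (sum(tab == best) > 1L) next # modal tie -> heterogeneous
    if (best > h * n_total[i]) hits <- hits + 1L
  }
  hits
}

#' Permutation test for the number of homogeneous families
#'
#' Permutes the module labels uniformly across the analysed paralogs
#' (preserving the label multiset), re-runs the family homogeneity rule for
#' each permutation, and reports the empirical p-value
#' `(#\{null >= observed\} + 1) / (n_permutations + 1)`.
#'
#' @inheritParams classify_families
#' @param n_permutations Number of label permutations (published setting 1000).
#' @param seed Integer RNG seed.
#' @return A `homogeneity_test` list: `observed`, `null_counts`,
#'   `empirical_p`, `n_permutations`.
#' @export
homogeneity_permutation_test <- function(modules, annotation,
                                         n_permutations = 1000, seed = 1L,
                                         homogeneity_fraction = 0.60) {
  stopifnot(n_permutations >= 1)
  ann <- tibble::as_tibble(annotation)
  mods <- tibble::as_tibble(modules)
  fam <- ann |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::inner_join(mods, by = "gene_id")
  fam_split <- split(seq_len(nrow(fam)), fam$family_id)
  n_total <- vapply(fam_split, function(i) fam$family_total_size[i[1]],
                    numeric(1))
  labels <- fam$module
  observed <- .count_homogeneous(labels, fam_split, n_total,
                                 homogeneity_fraction)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_permutations), function(b) {
    .count_homogeneous(sample(labels), fam_split, n_total,
                       homogeneity_fraction)
  }, integer(1))
  structure(
    list(
      observed = observed,
      null_counts = null_counts,
      empirical_p = (sum(null_counts >= observed) + 1) / (n_permutations + 1),
      n_permutations = as.integer(n_permutations)
    ),
    class = "homogeneity_test"
  )
}

#' @export
print.homogeneity_test <- function(x, ...) {
  cat(sprintf("<homogeneity_test> observed = %d homogeneous families\n",
              x$observed))
  cat(sprintf("  null: median %.1f, max %d over %d permutations; empirical p = %.4g\n",
              median(x$null_counts), max(x$null_counts), x$n_permutations,
              x$empirical_p))
  invisible(x)
}

#' @export
glance.homogeneity_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    null_median = median(x$null_counts),
    null_max = max(x$null_counts),
    empirical_p = x$empirical_p,
    n_permutations = x$n_permutations
  )
}
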