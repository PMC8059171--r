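#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the analysis in one validated object.
#' Defaults reproduce the published analysis settings: 1000 region-label
#' permutations, FDR 0.01 for the region-specificity call, a 0.1 RPKM
#' low-expression floor, a strict > 0.60 family homogeneity fraction and a
#' 1 Mb tandem-duplicate distance.
#'
#' @param n_permutations Number of region-label permutations for the Tau null.
#' @param fdr_alpha Benjamini-Hochberg q-value cutoff declaring a gene
#'   region-specific.
#' @param low_expr_rpkm Genes whose per-region mean RPKM stays below this in
#'   every region are filtered out.
#' @param lfc_threshold Absolute log2 fold-change cutoff kept for provenance
#'   when differential-expression lists are supplied externally (unused by
#'   the in-package stages).
#' @param homogeneity_fraction A family is homogeneous when strictly more
#'   than this fraction of its total members share one co-expression module.
#' @param majority_fraction A family is region-specific when strictly more
#'   than this fraction of its expressed members are specific to the same
#'   region.
#' @param tandem_bp Same-chromosome paralog pairs closer than this many base
#'   pairs are tandem duplicates.
#' @param rng_seed Integer seed recorded in all outputs.
#' @param soft_power Soft-thresholding power for the co-expression adjacency,
#'   or `"auto"` to pick the smallest power reaching the scale-free fit target.
#' @param min_module_size Smallest cluster kept as a module; smaller clusters
#'   become unassigned (label 0).
#' @param cut_height Dendrogram cut height on the topological-overlap
#'   dissimilarity (in (0, 1]).
#' @param deep_split Aggressiveness (0-4) of the recursive module splitting;
#'   higher values split at smaller dissimilarity gaps.
#' @param scale_free_r2_target Target signed R^2 for the `"auto"` soft power.
#' @return A `regiotau_config` list.
#' @export
#' @examples
#' cfg <- run_config(n_permutations = 100, rng_seed = 7)
#' config_hash(cfg)
run_config <- function(n_permutations = 1000,
                       fdr_alpha = 0.01,
                       low_expr_rpkm = 0.1,
                       lfc_threshold = 0.5,
                       homogeneity_fraction = 0.60,
                       majority_fraction = 0.5,
                       tandem_bp = 1e6L,
                       rng_seed = 1L,
                       soft_power = "auto",
                       min_module_size = 2L,
                       cut_height = 0.99,
                       deep_split = 4L,
                       scale_free_r2_target = 0.8) {
  stopifnot(
    n_permutations >= 1,
    fdr_alpha > 0, fdr_alpha < 1,
    low_expr_rpkm >= 0,
    homogeneity_fraction > 0, homogeneity_fraction < 1,
    majority_fraction > 0, majority_fraction < 1,
    tandem_bp > 0,
    min_module_size >= 1,
    cut_height > 0, cut_height <= 1,
    deep_split %in% 0:4,
    scale_free_r2_target > 0, scale_free_r2_target <= 1
  )
  if (!identical(soft_power, "auto")) {
    stopifnot(is.numeric(soft_power), soft_power >= 1)
  }
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      fdr_alpha = fdr_alpha,
      low_expr_rpkm = low_expr_rpkm,
      lfc_threshold = lfc_threshold,
      homogeneity_fraction = homogeneity_fraction,
      majority_fraction = majority_fraction,
      tandem_bp = as.integer(tandem_bp),
      rng_seed = as.integer(rng_seed),
      soft_power = soft_power,
      min_module_size = as.integer(min_module_size),
      cut_height = cut_height,
      deep_split = as.integer(deep_split),
      scale_free_r2_target = scale_free_r2_target
    ),
    class = "regiotau_config"
  )
}

#' @rdname run_config
#' @param config A `regiotau_config`.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "regiotau_config"))
  rlang::hash(unclass(config))
}

#' @export
print.regiotau_config <- function(x, ...) {
  cat("<regiotau_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
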