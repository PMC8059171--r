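.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full region-specificity pipeline
#'
#' Chains every analysis stage on files: read and validate the inputs,
#' filter / log-transform / covariate-adjust the expression matrix, compute
#' Tau with its permutation null and region-specificity calls, run the
#' standard duplication-category enrichment battery, infer co-expression
#' modules over the expressed paralogs, classify families (homogeneity and
#' region-specificity), build reciprocal pairs with genomic distance
#' classes, and write six TSV result tables, each under a provenance header
#' carrying the package version, seed and configuration hash. Given the
#' same configuration (including `rng_seed`) the outputs are byte-identical
#' across runs.
#'
#' @param expression Path to the expression matrix (GCT 1.2 or TSV, RPKM).
#' @param samples Path to the sample attribute TSV.
#' @param annotation Path to the gene annotation TSV.
#' @param outdir Output directory (created if needed).
#' @param config A [run_config()].
#' @param pair_list Optional tibble of raw pair orientations (`gene_a`,
#'   `gene_b`, `dup_category`); when `NULL`, both orientations of every
#'   size-2 family sharing one duplication category are used.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(expression, samples, annotation, outdir,
                         config = run_config(), pair_list = NULL) {
  stopifnot(inherits(config, "regiotau_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  m <- .stage("read_expression", read_expression(expression))
  smp <- .stage("read_samples", read_samples(samples))
  ann <- .stage("read_annotation", read_annotation(annotation))

  # the analysis universe is the annotated genes present in the matrix
  known <- intersect(rownames(m), ann$gene_id)
  dropped <- nrow(m) - length(known)
  if (dropped > 0) {
    inform(sprintf("run_pipeline: %d unannotated matrix gene(s) dropped", dropped))
  }
  if (length(known) == 0L) abort("no matrix genes present in the annotation")
  m <- expr_matrix(unclass(m)[known, , drop = FALSE], transform_state(m))

  adj <- .stage("preprocess", {
    m |>
      filter_genes(smp, low_expr_rpkm = config$low_expr_rpkm) |>
      log_transform() |>
      adjust_covariates(smp)
  })
  ann <- ann[ann$gene_id %in% rownames(adj), , drop = FALSE]

  calls <- .stage("tau", tau_specificity(
    adj, smp, n_permutations = config$n_permutations,
    fdr_alpha = config$fdr_alpha, seed = config$rng_seed))

  enrich <- .stage("enrich", standard_enrichment(calls, ann))

  paralogs <- ann$gene_id[ann$status == "paralog"]
  mods <- .stage("modules", infer_modules(
    expr_matrix(unclass(adj)[rownames(adj) %in% paralogs, , drop = FALSE],
                "adjusted"),
    soft_power = config$soft_power,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height, deep_split = config$deep_split,
    scale_free_r2_target = config$scale_free_r2_target))

  fams <- .stage("families", classify_families(
    mods, ann, homogeneity_fraction = config$homogeneity_fraction))
  fam_spec <- .stage("families", classify_family_specificity(
    calls, ann, majority_fraction = config$majority_fraction))
  fam_tbl <- dplyr::full_join(
    fams, dplyr::rename(fam_spec, specificity_status = "status"),
    by = "family_id")

  if (is.null(pair_list)) {
    pair_list <- .pairs_from_families(ann)
  }
  pairs <- .stage("pairs", {
    build_pairs(pair_list) |>
      classify_distance(ann, tandem_bp = config$tandem_bp)
  })
  shared <- pair_shared_specificity(pairs, calls)
  pairs <- dplyr::left_join(
    pairs,
    dplyr::select(calls$results, "gene_id", spec_a = "is_region_specific",
                  region_a = "assigned_region"),
    by = c(gene_a = "gene_id")) |>
    dplyr::left_join(
      dplyr::select(calls$results, "gene_id", spec_b = "is_region_specific",
                    region_b = "assigned_region"),
      by = c(gene_b = "gene_id"))

  paths <- c(
    preprocessed = "preprocessed_matrix.tsv",
    tau = "tau_results.tsv",
    enrichment = "enrichment.tsv",
    modules = "module_assignment.tsv",
    families = "family_classification.tsv",
    pairs = "pair_distances.tsv"
  )
  paths <- setNames(file.path(outdir, paths), names(paths))
  .write_result(tibble::as_tibble(unclass(adj), rownames = "gene_id"),
                paths["preprocessed"], config, "preprocess")
  tau_out <- calls$results
  tau_out$tau_threshold <- calls$tau_threshold
  .write_result(tau_out, paths["tau"], config, "tau")
  .write_result(enrich, paths["enrichment"], config, "enrich")
  .write_result(tibble::as_tibble(mods), paths["modules"], config, "modules")
  .write_result(fam_tbl, paths["families"], config, "families")
  .write_result(pairs, paths["pairs"], config, "pairs")
  invisible(as.list(paths))
}

# both orientations of every size-2 family with a single duplication
# category: the simulator's family structure doubles as a pair list
.pairs_from_families <- function(annotation) {
  ann <- tibble::as_tibble(annotation)
  twos <- ann |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(dplyr::n() == 2L,
                  dplyr::n_distinct(.data$dup_category) == 1L) |>
    dplyr::summarise(gene_a = min(.data$gene_id),
                     gene_b = max(.data$gene_id),
                     dup_category = .data$dup_category[1],
                     .groups = "drop")
  dplyr::bind_rows(
    dplyr::select(twos, "gene_a", "gene_b", "dup_category"),
    dplyr::select(twos, gene_a = "gene_b", gene_b = "gene_a",
                  "dup_category")
  )
}

#' The standard duplication-category enrichment battery
#'
#' The seven region-specificity contingency tests of the published Table:
#' paralogs within all genes; WGD, SSD and ySSD within paralogs; ySSD and
#' oSSD within SSDs; wSSD within the WGD + wSSD pool. Bonferroni family
#' size 7.
#'
#' @param calls A `tau_calls` object or its `results` tibble.
#' @param annotation Annotation tibble with `status`, `dup_category`,
#'   `ssd_age`.
#' @param exclude Optional gene ids excluded from every universe.
#' @return A tibble with one row per test (the [enrichment_counts()]
#'   columns).
#' @export
standard_enrichment <- function(calls, annotation, exclude = NULL) {
  res <- if (inherits(calls, "tau_calls")) calls$results else
    tibble::as_tibble(calls)
  d <- dplyr::inner_join(res, tibble::as_tibble(annotation), by = "gene_id")
  if (!is.null(exclude)) d <- dplyr::filter(d, !.data$gene_id %in% exclude)
  d <- dplyr::mutate(
    d,
    specific = .data$is_region_specific %in% TRUE,
    paralog = .data$status == "paralog",
    wgd = .data$dup_category == "WGD",
    ssd = .data$dup_category == "SSD",
    yssd = .data$ssd_age == "ySSD",
    ossd = .data$ssd_age == "oSSD",
    wssd = .data$ssd_age == "wSSD"
  )
  para <- dplyr::filter(d, .data$paralog)
  ssd <- dplyr::filter(d, .data$ssd)
  wgd_wssd <- dplyr::filter(d, .data$wgd | .data$wssd)
  dplyr::bind_rows(
    enrichment_test(d, .data$paralog, .data$specific,
                    "paralogs", "protein coding", n_tests = 7L),
    enrichment_test(para, .data$wgd, .data$specific,
                    "WGD", "paralogs", n_tests = 7L),
    enrichment_test(para, .data$ssd, .data$specific,
                    "SSD", "paralogs", n_tests = 7L),
    enrichment_test(para, .data$yssd, .data$specific,
                    "ySSD", "paralogs", n_tests = 7L),
    enrichment_test(ssd, .data$yssd, .data$specific,
                    "ySSD", "SSD", n_tests = 7L),
    enrichment_test(ssd, .data$ossd, .data$specific,
                    "oSSD", "SSD", n_tests = 7L),
    enrichment_test(wgd_wssd, .data$wssd, .data$specific,
                    "wSSD", "WGD+wSSD", n_tests = 7L)
  )
}
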