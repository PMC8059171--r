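#' Classify gene families as region-specific
#'
#' A family is region-specific when strictly more than `majority_fraction`
#' (default: half) of its expressed members are called region-specific and
#' assigned to the same territory. The major region is the modal assigned
#' region among the family's specific members; a modal tie makes the family
#' not region-specific.
#'
#' @param calls A `tau_calls` object or its `results` tibble.
#' @param annotation Annotation tibble (`gene_id`, `family_id`).
#' @param majority_fraction Strict lower bound on the same-region fraction
#'   of expressed members (default 0.5).
#' @return A tibble: `family_id`, `n_expressed`, `n_specific`,
#'   `major_region`, `n_in_major`, `status` (`region_specific` /
#'   `not_region_specific`).
#' @export
classify_family_specificity <- function(calls, annotation,
                                        majority_fraction = 0.5) {
  res <- if (inherits(calls, "tau_calls")) calls$results else
    tibble::as_tibble(calls)
  ann <- tibble::as_tibble(annotation)
  fam <- ann |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::inner_join(res, by = "gene_id")
  fam |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(df, key) {
      spec <- df[df$is_region_specific %in% TRUE, ]
      major_region <- NA_character_
      n_in_major <- 0L
      if (nrow(spec) > 0) {
        tab <- sort(table(spec$assigned_region), decreasing = TRUE)
        if (length(tab) == 1L || tab[1] > tab[2]) {
          major_region <- names(tab)[1]
          n_in_major <- as.integer(tab[1])
        }
      }
      tibble::tibble(
        n_expressed = nrow(df),
        n_specific = nrow(spec),
        major_region = major_region,
        n_in_major = n_in_major,
        status = ifelse(n_in_major > majority_fraction * nrow(df),
                        "region_specific", "not_region_specific")
      )
    }) |>
    dplyr::ungroup()
}

#' Build reciprocal paralog pairs
#'
#' Keeps only pairs listed in both orientations with the same duplication
#' category (the reciprocity rule for pair-level analyses); pairs whose two
#' orientations disagree on the category are dropped with a message. The
#' output is deduplicated in canonical (lexicographic) orientation.
#'
#' @param pair_list Tibble with columns `gene_a`, `gene_b`, `dup_category`
#'   (one row per listed orientation).
#' @return A tibble: `gene_a < gene_b`, `dup_category`, `reciprocal`
#'   (always `TRUE` for retained pairs).
#' @export
build_pairs <- function(pair_list) {
  pl <- tibble::as_tibble(pair_list) |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b),
      forward = .data$gene_a == .data$lo
    )
  canon <- pl |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(
      n_orient = dplyr::n_distinct(.data$forward),
      n_cat = dplyr::n_distinct(.data$dup_category),
      dup_category = .data$dup_category[1],
      .groups = "drop"
    )
  conflicted <- canon |> dplyr::filter(.data$n_orient == 2L, .data$n_cat > 1L)
  if (nrow(conflicted) > 0) {
    inform(sprintf("build_pairs: %d pair(s) dropped for conflicting categories between orientations", nrow(conflicted)))
  }
  canon |>
    dplyr::filter(.data$n_orient == 2L, .data$n_cat == 1L) |>
    dplyr::transmute(
      gene_a = .data$lo, gene_b = .data$hi,
      dup_category = .data$dup_category,
      reciprocal = TRUE
    )
}

#' Classify the genomic distance of paralog pairs
#'
#' Pairs on different chromosomes are `inter_chromosomal`; same-chromosome
#' pairs with start coordinates closer than `tandem_bp` (default 1 Mb) are
#' `tandem`, otherwise `intra_chromosomal`. Start-to-start distance is used:
#' it is strand-free and deterministic. Pairs with a missing coordinate get
#' class `unknown` and are excluded from distance tests.
#'
#' @param pairs Tibble from [build_pairs()].
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `start`).
#' @param tandem_bp Distance bound (base pairs) below which a
#'   same-chromosome pair is tandem (default 1 Mb).
#' @return `pairs` with added `distance_bp` (`NA` across chromosomes) and
#'   `distance_class`.
#' @export
classify_distance <- function(pairs, annotation, tandem_bp = 1e6) {
  ann <- dplyr::select(tibble::as_tibble(annotation),
                       "gene_id", "chrom", "start")
  out <- tibble::as_tibble(pairs) |>
    dplyr::left_join(ann, by = c(gene_a = "gene_id")) |>
    dplyr::rename(chrom_a = "chrom", start_a = "start") |>
    dplyr::left_join(ann, by = c(gene_b = "gene_id")) |>
    dplyr::rename(chrom_b = "chrom", start_b = "start")
  out |>
    dplyr::mutate(
      same_chrom = .data$chrom_a == .data$chrom_b,
      distance_bp = ifelse(.data$same_chrom,
                           abs(.data$start_a - .data$start_b), NA_real_),
      distance_class = dplyr::case_when(
        is.na(.data$chrom_a) | is.na(.data$chrom_b) |
          is.na(.data$start_a) | is.na(.data$start_b) ~ "unknown",
        !.data$same_chrom ~ "inter_chromosomal",
        .data$distance_bp < tandem_bp ~ "tandem",
        TRUE ~ "intra_chromosomal"
      )
    ) |>
    dplyr::select(-"same_chrom", -"chrom_a", -"chrom_b",
                  -"start_a", -"start_b")
}

#' Shared region-specificity of paralog pairs by duplication category
#'
#' Among pairs whose two members are both called region-specific, the
#' fraction assigned to the same territory, reported per duplication
#' category with the underlying counts (small denominators are visible
#' rather than hidden in a percentage).
#'
#' @param pairs Tibble from [build_pairs()] (optionally with distance
#'   classes).
#' @param calls A `tau_calls` object or its `results` tibble.
#' @return A tibble per `dup_category`: `n_pairs`, `n_both_specific`,
#'   `n_same_region`, `frac_same_region`.
#' @export
pair_shared_specificity <- function(pairs, calls) {
  res <- if (inherits(calls, "tau_calls")) calls$results else
    tibble::as_tibble(calls)
  res <- dplyr::select(res, "gene_id", "is_region_specific",
                       "assigned_region")
  tibble::as_tibble(pairs) |>
    dplyr::left_join(res, by = c(gene_a = "gene_id")) |>
    dplyr::rename(spec_a = "is_region_specific", region_a = "assigned_region") |>
    dplyr::left_join(res, by = c(gene_b = "gene_id")) |>
    dplyr::rename(spec_b = "is_region_specific", region_b = "assigned_region") |>
    dplyr::mutate(
      both_specific = .data$spec_a %in% TRUE & .data$spec_b %in% TRUE,
      same_region = .data$both_specific & .data$region_a == .data$region_b
    ) |>
    dplyr::group_by(.data$dup_category) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_both_specific = sum(.data$both_specific, na.rm = TRUE),
      n_same_region = sum(.data$same_region, na.rm = TRUE),
      frac_same_region = ifelse(.data$n_both_specific > 0,
                                .data$n_same_region / .data$n_both_specific,
                                NA_real_),
      .groups = "drop"
    )
}
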