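#' Contingency enrichment test from 2x2 counts
#'
#' Core of the duplication-category enrichment tables. The table is
#' `[[a, b], [c, d]]` with rows = tested group / rest of the universe and
#' columns = property yes / no. A chi-squared test without continuity
#' correction is used unless any expected count falls below 5, in which case
#' Fisher's exact test (two-sided) is applied. The odds ratio is the
#' unconditional sample cross-product ratio `(a d) / (b c)` (infinite, with
#' a warning, when `b c = 0`).
#'
#' @param a,b,c,d Non-negative integer counts: `a` tested genes with the
#'   property, `b` tested without, `c` remaining genes with, `d` remaining
#'   without.
#' @param tested_label,reference_label Group labels carried into the result.
#' @param n_tests Number of tests in the family, for the Bonferroni
#'   threshold column (`0.05 / n_tests`).
#' @return A one-row `enrichment_result` tibble: `tested_group`,
#'   `reference_group`, `n_tested`, `n_universe`, `pct_tested`, `statistic`,
#'   `p_value`, `test_used`, `odds_ratio`, `bonferroni_threshold`; the 2x2
#'   table is attached as attribute `"table"`.
#' @export
#' @examples
#' enrichment_counts(1984, 8351, 845, 5247,
#'                   tested_label = "paralogs",
#'                   reference_label = "protein coding")
enrichment_counts <- function(a, b, c, d,
                              tested_label = "tested",
                              reference_label = "reference",
                              n_tests = 1L) {
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4L, all(counts >= 0), n_tests >= 1)
  if (a + b == 0L) abort("empty tested group")
  if (c + d == 0L) abort("empty complement of the tested group")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE,
                dimnames = list(c("tested", "other"), c("yes", "no")))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    statistic <- NA_real_
    p_value <- ft$p.value
    test_used <- "fisher"
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    statistic <- unname(ct$statistic)
    p_value <- ct$p.value
    test_used <- "chi_squared"
  }
  if (b * c == 0 && a * d > 0) {
    warn("odds ratio is infinite (a zero off-diagonal cell)")
  }
  out <- tibble::tibble(
    tested_group = tested_label,
    reference_group = reference_label,
    n_tested = a + b,
    n_universe = n,
    pct_tested = 100 * a / (a + b),
    statistic = statistic,
    p_value = p_value,
    test_used = test_used,
    odds_ratio = (a * d) / (b * c),
    bonferroni_threshold = bonferroni_threshold(0.05, n_tests)
  )
  attr(out, "table") <- tab
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Contingency enrichment test on a gene table
#'
#' Data-frame interface to [enrichment_counts()]: given per-gene logical
#' columns marking membership of the tested subset and possession of the
#' property, builds the 2x2 table over the supplied universe (optionally
#' minus an exclusion set) and runs the test.
#'
#' @param data A data frame (the gene universe), one row per gene.
#' @param tested,property Unquoted logical columns of `data`.
#' @param tested_label,reference_label Labels for the output (defaults are
#'   the column names).
#' @param n_tests Bonferroni family size.
#' @param exclude Optional character vector of `gene_id`s to drop from the
#'   universe before testing (e.g. the non-co-expressed members of
#'   homogeneous families).
#' @return A one-row `enrichment_result` tibble (see [enrichment_counts()]).
#' @export
enrichment_test <- function(data, tested, property,
                            tested_label = NULL, reference_label = "universe",
                            n_tests = 1L, exclude = NULL) {
  data <- tibble::as_tibble(data)
  tested_q <- rlang::enquo(tested)
  property_q <- rlang::enquo(property)
  if (is.null(tested_label)) tested_label <- rlang::as_label(tested_q)
  if (!is.null(exclude)) {
    if (!"gene_id" %in% names(data)) {
      abort("`exclude` needs a gene_id column in `data`")
    }
    data <- dplyr::filter(data, !.data$gene_id %in% exclude)
  }
  t_vec <- rlang::eval_tidy(tested_q, data)
  p_vec <- rlang::eval_tidy(property_q, data)
  if (!is.logical(t_vec) || !is.logical(p_vec)) {
    abort("`tested` and `property` must evaluate to logical vectors")
  }
  ok <- !is.na(t_vec) & !is.na(p_vec)
  t_vec <- t_vec[ok]; p_vec <- p_vec[ok]
  enrichment_counts(
    sum(t_vec & p_vec), sum(t_vec & !p_vec),
    sum(!t_vec & p_vec), sum(!t_vec & !p_vec),
    tested_label = tested_label, reference_label = reference_label,
    n_tests = n_tests
  )
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (e.g. 0.05).
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 78) # the 13-region pairwise family
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Compare Tau between two gene groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test (normal approximation with tie
#' correction) with group medians.
#'
#' @param group_a,group_b Numeric vectors of Tau scores.
#' @return A one-row tibble: `statistic` (the U statistic for `group_a`),
#'   `p_value`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
rank_compare_tau <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be nonempty")
  }
  wt <- wilcox.test(group_a, group_b, exact = FALSE, correct = FALSE)
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    median_a = median(group_a),
    median_b = median(group_b),
    n_a = length(group_a),
    n_b = length(group_b)
  )
}

#' Linear models of Tau on expression and duplication status
#'
#' Ordinary least squares of the Tau score on the maximal territory
#' expression plus duplication-status indicators, in the three standard
#' designs: `"paralog"` (all genes; paralog vs singleton indicator),
#' `"dup_type"` (paralogs only; WGD / SSD / WGD_SSD / unannotated
#' indicators) and `"ssd_age"` (SSD genes only; ySSD / wSSD / oSSD
#' indicators).
#'
#' @param data Tibble with columns `tau`, `max_region_mean` and the
#'   annotation columns `status`, `dup_category`, `ssd_age` (e.g. Tau
#'   results joined to the annotation).
#' @param design One of `"paralog"`, `"dup_type"`, `"ssd_age"`, or a
#'   formula for a custom design.
#' @return A `tau_lm` object (an `lm`); use [tidy()] / [glance()] for the
#'   coefficient and fit tables.
#' @export
tau_linear_model <- function(data, design = c("paralog", "dup_type", "ssd_age")) {
  data <- tibble::as_tibble(data)
  if (inherits(design, "formula")) {
    form <- design
    design_name <- "custom"
  } else {
    design_name <- match.arg(design)
    data <- switch(design_name,
      paralog = dplyr::mutate(data, is_paralog = .data$status == "paralog"),
      dup_type = dplyr::filter(data, .data$status == "paralog") |>
        dplyr::mutate(dup_category = factor(.data$dup_category,
          levels = c("WGD", "SSD", "WGD_SSD", "unannotated"))),
      ssd_age = dplyr::filter(data, .data$dup_category == "SSD") |>
        dplyr::mutate(ssd_age = factor(.data$ssd_age,
          levels = c("oSSD", "wSSD", "ySSD")))
    )
    form <- switch(design_name,
      paralog = tau ~ max_region_mean + is_paralog,
      dup_type = tau ~ max_region_mean + dup_category,
      ssd_age = tau ~ max_region_mean + ssd_age
    )
  }
  mm <- model.matrix(form, data = data)
  if (qr(mm)$rank < ncol(mm)) {
    qrx <- qr(mm)
    dropped <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    abort(paste0("collinear design; offending term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- lm(form, data = data)
  class(fit) <- c("tau_lm", class(fit))
  attr(fit, "design") <- design_name
  fit
}

#' @export
tidy.tau_lm <- function(x, ...) {
  cf <- summary(x)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
}

#' @export
glance.tau_lm <- function(x, ...) {
  s <- summary(x)
  tibble::tibble(
    design = attr(x, "design") %||% "custom",
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = length(s$residuals),
    df_residual = x$df.residual
  )
}
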