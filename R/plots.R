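#' Plot observed vs permuted Tau distributions
#'
#' Density of the observed Tau scores overlaid on the pooled permutation
#' null, with the calibrated region-specificity threshold as a vertical
#' line.
#'
#' @param x A `tau_calls` object whose null was kept (as returned by
#'   [tau_specificity()]), or pass `null` explicitly.
#' @param null A `tau_null` (defaults to `x$null`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_tau_distribution <- function(x, null = x$null, ...) {
  stopifnot(inherits(x, "tau_calls"))
  if (is.null(null)) abort("no null distribution available; pass `null`")
  obs <- tibble::tibble(tau = x$results$tau[!is.na(x$results$tau)],
                        which = "observed")
  # the pooled null can be huge; a fixed-seed thinning keeps plotting fast
  ns <- null$pooled_scores
  if (length(ns) > 2e5) ns <- ns[seq(1, length(ns), length.out = 2e5)]
  dat <- dplyr::bind_rows(obs, tibble::tibble(tau = ns, which = "permuted"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau, colour = .data$which)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = x$tau_threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(observed = "#2c7bb6",
                                            permuted = "#9e66ab")) +
    ggplot2::labs(x = "Tau", y = "density", colour = NULL,
                  title = sprintf("Region-specificity threshold: tau >= %.3f",
                                  x$tau_threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tau_calls <- function(object, ...) plot_tau_distribution(object, ...)

#' Plot gene counts and specificity rates by expression bin
#'
#' Two-panel view of [bin_by_expression()] output: per-bin gene counts and
#' per-bin percentage of region-specific genes, coloured by gene class.
#'
#' @param bins A tibble from [bin_by_expression()].
#' @param what `"pct_specific"` (default) or `"n_genes"`.
#' @return A ggplot object.
#' @export
plot_expression_bins <- function(bins, what = c("pct_specific", "n_genes")) {
  what <- match.arg(what)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data[[what]],
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "max territory mean, log2(RPKM + 1) bin",
                  y = if (what == "pct_specific")
                    "% region-specific" else "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the module size distribution
#'
#' @param modules A `module_assignment` tibble from [infer_modules()].
#' @return A ggplot object.
#' @export
plot_module_sizes <- function(modules) {
  sizes <- attr(modules, "module_sizes")
  if (is.null(sizes)) {
    sizes <- modules |>
      dplyr::filter(.data$module > 0) |>
      dplyr::count(.data$module, name = "size")
  }
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "module size (genes)", y = "modules") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_assignment <- function(object, ...) plot_module_sizes(object)

#' Plot Tau by phyletic age group
#'
#' Median and interquartile band of Tau against phyletic age, with the
#' region-specificity threshold as a horizontal reference when supplied.
#'
#' @param ages A tibble from [tau_by_phyletic_age()].
#' @param tau_threshold Optional threshold line.
#' @return A ggplot object.
#' @export
plot_tau_by_age <- function(ages, tau_threshold = NULL) {
  p <- ggplot2::ggplot(ages, ggplot2::aes(x = .data$phyletic_age,
                                          y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "phyletic age", y = "Tau (median, IQR band)") +
    ggplot2::theme_minimal()
  if (!is.null(tau_threshold) && is.finite(tau_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = tau_threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}
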