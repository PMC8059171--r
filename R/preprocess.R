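# per-r13-region averaging matrix (samples x 13), columns in .REGIONS_13 order
.indicator_13 <- function(region_13) {
  f <- factor(region_13, levels = .REGIONS_13)
  present <- levels(f)[tabulate(f, nbins = 13L) > 0]
  ind <- matrix(0, length(f), length(present),
                dimnames = list(NULL, present))
  ind[cbind(seq_along(f), match(as.character(f), present))] <- 1
  sweep(ind, 2, colSums(ind), "/")
}

# 13 -> 7 unweighted averaging matrix for the r13 regions actually present
.merge_weights <- function(r13_present) {
  r7 <- .to_region_7(r13_present)
  out <- matrix(0, length(r13_present), length(.REGIONS_7),
                dimnames = list(r13_present, .REGIONS_7))
  out[cbind(seq_along(r13_present), match(r7, .REGIONS_7))] <- 1
  keep <- colSums(out) > 0
  out <- out[, keep, drop = FALSE]
  sweep(out, 2, colSums(out), "/")
}

#' Filter uninformative genes
#'
#' Drops genes with null variance across all samples, then genes whose mean
#' RPKM is below `low_expr_rpkm` in every one of the 13 regions. Removal
#' counts by reason are reported as messages.
#'
#' @param m An [expr_matrix()] in the `raw_rpkm` state.
#' @param samples Sample attribute table covering every column of `m`.
#' @param low_expr_rpkm Per-region mean RPKM floor (default 0.1).
#' @return The filtered `raw_rpkm` matrix.
#' @export
filter_genes <- function(m, samples, low_expr_rpkm = 0.1) {
  .check_state(m, "raw_rpkm", "filter_genes()")
  samples <- .match_samples(m, samples)
  v <- unclass(m)
  mu <- rowMeans(v)
  varying <- rowSums((v - mu)^2) > 0
  means13 <- v %*% .indicator_13(samples$region_13)
  expressed <- apply(means13, 1L, max) >= low_expr_rpkm
  inform(sprintf("filter_genes: removed %d null-variance and %d weakly expressed of %d genes",
                 sum(!varying), sum(varying & !expressed), nrow(v)))
  keep <- varying & expressed
  if (!any(keep)) abort("no genes pass filters")
  expr_matrix(v[keep, , drop = FALSE], "raw_rpkm")
}

#' Log-transform RPKM values
#'
#' Elementwise `log2(RPKM + 1)`.
#'
#' @inheritParams filter_genes
#' @return An `expr_matrix` in the `log2p1` state.
#' @export
log_transform <- function(m) {
  .check_state(m, "raw_rpkm", "log_transform()")
  if (any(m < 0)) abort("negative RPKM values cannot be log-transformed")
  .set_state(log2(unclass(m) + 1), "log2p1")
}

#' Adjust expression for technical and biological covariates
#'
#' Per gene, ordinary least squares of log2(RPKM + 1) on sequencing platform,
#' age, sex and the first three genotype principal components; the output is
#' the residuals plus the fitted intercept, so between-gene mean differences
#' are preserved. Categorical covariates use treatment coding with the most
#' frequent level as reference; single-level covariates are dropped from the
#' design (they are absorbed by the intercept).
#'
#' @param m An `expr_matrix` in the `log2p1` state.
#' @param samples Sample attribute table with complete covariates.
#' @param covariates Covariate column names (defaults to the standard six).
#' @return An `expr_matrix` in the `adjusted` state. Adjusted values may be
#'   negative; downstream Tau computation clips negatives to zero.
#' @export
adjust_covariates <- function(m, samples,
                              covariates = c("platform", "age", "sex",
                                             "pc1", "pc2", "pc3")) {
  .check_state(m, "log2p1", "adjust_covariates()")
  samples <- .match_samples(m, samples)
  dat <- samples[, covariates, drop = FALSE]
  # factors: most frequent level first (treatment-coding reference);
  # single-level terms carry no information and are dropped
  keep <- character(0)
  for (cv in covariates) {
    x <- dat[[cv]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- sort(table(as.character(x)), decreasing = TRUE)
      if (length(tab) < 2L) next
      dat[[cv]] <- factor(as.character(x), levels = names(tab))
    } else if (length(unique(x)) < 2L) {
      next
    }
    keep <- c(keep, cv)
  }
  if (length(keep) == 0L) {
    # intercept-only fit: residuals + intercept give back the input
    return(.set_state(unclass(m), "adjusted"))
  }
  X <- model.matrix(stats::reformulate(keep), data = dat)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient covariate design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  v <- unclass(m)
  coef <- t(qr.coef(qrx, t(v)))        # genes x p
  fitted <- coef %*% t(X)
  out <- v - fitted + coef[, "(Intercept)"]
  .set_state(out, "adjusted")
}

#' Per-region mean expression
#'
#' At the 13-region level each mean is the plain average over that region's
#' samples. At the 7-region level a territory's mean is the unweighted
#' average of its constituent 13-region means, not the pooled sample mean,
#' so unequal sampling of sub-regions does not bias the merged value.
#'
#' @param m An `expr_matrix` (any transform state).
#' @param samples Sample attribute table covering every column of `m`.
#' @param level `"r7"` (default) or `"r13"`.
#' @return A gene x region numeric matrix with region column names.
#' @export
region_means <- function(m, samples, level = c("r7", "r13")) {
  level <- match.arg(level)
  samples <- .match_samples(m, samples)
  ind <- .indicator_13(samples$region_13)
  means13 <- unclass(m) %*% ind
  if (level == "r13") return(means13)
  means13 %*% .merge_weights(colnames(means13))
}
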