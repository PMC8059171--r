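#' Expression matrix container
#'
#' A gene x sample numeric matrix of bulk RNA-seq abundances with a recorded
#' transformation state. Values start life as RPKM (`raw_rpkm`), become
#' `log2p1` after [log_transform()] and `adjusted` after
#' [adjust_covariates()]. All analysis functions check the state they
#' require, so a matrix cannot silently be fed to a step in the wrong units.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param transform One of `"raw_rpkm"`, `"log2p1"`, `"adjusted"`.
#' @return An `expr_matrix`: the matrix with a `transform_state` attribute.
#' @export
#' @examples
#' m <- expr_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' transform_state(m)
expr_matrix <- function(values, transform = c("raw_rpkm", "log2p1", "adjusted")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    abort("`values` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at gene '%s', sample '%s'",
                  gid[idx[1]], sid[idx[2]]))
  }
  if (transform == "raw_rpkm" && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative RPKM at gene '%s', sample '%s'",
                  gid[idx[1]], sid[idx[2]]))
  }
  structure(values, transform_state = transform,
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
transform_state <- function(x) {
  attr(x, "transform_state") %||% "raw_rpkm"
}

.check_state <- function(x, expected, what) {
  if (!identical(transform_state(x), expected)) {
    abort(sprintf("%s expects a '%s' matrix, got '%s'",
                  what, expected, transform_state(x)))
  }
  invisible(x)
}

.set_state <- function(x, transform) {
  attr(x, "transform_state") <- transform
  class(x) <- c("expr_matrix", "matrix", "array")
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), transform_state(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4), ...)
  invisible(x)
}

#' Long-format view of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param ... Ignored.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Validate a sample attribute table
#'
#' Checks the columns the pipeline relies on: `sample_id` (unique),
#' `region_13` (one of the 13 region names) and complete covariates
#' `platform`, `age`, `sex`, `pc1`..`pc3`. A `region_7` column is derived
#' from `region_13` via the fixed merge map (and checked if already present).
#'
#' @param samples A data frame of per-sample attributes.
#' @return The validated tibble with `region_7` filled in.
#' @export
validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "region_13", "platform", "age", "sex",
            "pc1", "pc2", "pc3")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample ids in sample table")
  }
  r7 <- .to_region_7(samples$region_13)
  if ("region_7" %in% names(samples) &&
      !identical(unname(as.character(samples$region_7)), r7)) {
    abort("region_7 column disagrees with the fixed 13 -> 7 merge map")
  }
  samples$region_7 <- r7
  covars <- c("platform", "age", "sex", "pc1", "pc2", "pc3")
  for (cv in covars) {
    if (anyNA(samples[[cv]])) {
      abort(sprintf("covariate '%s' has missing values; adjustment requires complete covariates", cv))
    }
  }
  samples
}

.match_samples <- function(m, samples) {
  samples <- validate_samples(samples)
  miss <- setdiff(colnames(m), samples$sample_id)
  if (length(miss) > 0) {
    abort(paste0("samples absent from sample table: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  samples[match(colnames(m), samples$sample_id), , drop = FALSE]
}
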