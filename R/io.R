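#' Read an expression matrix from GCT 1.2 or plain TSV
#'
#' The GCT dialect is the two-header-line format shipped with GTEx releases:
#' line 1 is `#1.2`, line 2 declares `n_genes<TAB>n_samples`, then a header
#' row `Name`, `Description`, sample ids. Only version 1.2 is accepted. The
#' TSV dialect has gene ids in the first column and one column per sample.
#'
#' @param path Path to the file.
#' @param format `"gct"`, `"tsv"`, or `"auto"` (by extension, `.gct` vs rest).
#' @return An [expr_matrix()] in the `raw_rpkm` state.
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") .read_gct(path) else .read_expr_tsv(path)
}

.read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L) abort("malformed GCT: fewer than 2 header lines")
  if (!identical(trimws(header[1]), "#1.2")) {
    abort(paste0("unsupported GCT version line: '", header[1],
                 "' (only #1.2 is accepted)"))
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(header[2]), "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    abort(paste0("malformed GCT dimension line: '", header[2], "'"))
  }
  body <- readr::read_tsv(path, skip = 2L, show_col_types = FALSE,
                          progress = FALSE)
  if (!identical(names(body)[1:2], c("Name", "Description"))) {
    abort("malformed GCT: first columns must be 'Name' and 'Description'")
  }
  values <- as.matrix(body[, -(1:2), drop = FALSE])
  rownames(values) <- as.character(body$Name)
  if (nrow(values) != dims[1] || ncol(values) != dims[2]) {
    abort(sprintf(
      "GCT header declares %d x %d but body is %d x %d",
      dims[1], dims[2], nrow(values), ncol(values)))
  }
  expr_matrix(values, "raw_rpkm")
}

.read_expr_tsv <- function(path) {
  body <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(body[, -1, drop = FALSE])
  rownames(values) <- as.character(body[[1]])
  expr_matrix(values, "raw_rpkm")
}

#' Write an expression matrix
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @param format `"gct"` (1.2) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  tbl <- tibble::as_tibble(unclass(x), rownames = "gene_id")
  if (format == "tsv") {
    readr::write_tsv(tbl, path, progress = FALSE)
  } else {
    gct <- tibble::add_column(tbl, Description = tbl$gene_id, .after = 1L)
    names(gct)[1] <- "Name"
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), path)
    readr::write_tsv(gct, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a sample attribute table
#'
#' @param path TSV with columns `sample_id`, `region_13`, `platform`, `age`,
#'   `sex`, `pc1`, `pc2`, `pc3` (a `region_7` column, if present, is checked
#'   against the fixed merge map).
#' @return A validated tibble with `region_7` filled in.
#' @export
read_samples <- function(path) {
  validate_samples(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
}

.DUP_CATEGORIES <- c("WGD", "SSD", "WGD_SSD", "unannotated", "none")
.SSD_AGES <- c("ySSD", "wSSD", "oSSD", "not_applicable")

#' Validate a gene annotation table
#'
#' Enforces the annotation invariants: `ssd_age` other than
#' `not_applicable` only on SSD genes; singletons carry `dup_category =
#' "none"` and no family; `family_total_size` at least the number of
#' annotated members carrying the family id.
#'
#' @param annotation Data frame with columns `gene_id`, `status`
#'   (`paralog`/`singleton`), `dup_category`, `ssd_age`, `family_id`,
#'   `family_total_size`, `phyletic_age`, `chrom`, `start`.
#' @return The validated tibble.
#' @export
validate_annotation <- function(annotation) {
  ann <- tibble::as_tibble(annotation)
  need <- c("gene_id", "status", "dup_category", "ssd_age", "family_id",
            "family_total_size", "phyletic_age", "chrom", "start")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    abort(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(ann$gene_id)) {
    abort(paste0("duplicate gene ids in annotation: ",
                 paste(unique(ann$gene_id[duplicated(ann$gene_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(ann$status), c("paralog", "singleton"))
  if (length(bad) > 0) abort(paste0("unknown status value(s): ",
                                    paste(bad, collapse = ", ")))
  bad <- setdiff(unique(ann$dup_category), .DUP_CATEGORIES)
  if (length(bad) > 0) abort(paste0("unknown dup_category value(s): ",
                                    paste(bad, collapse = ", ")))
  bad <- setdiff(unique(ann$ssd_age), .SSD_AGES)
  if (length(bad) > 0) abort(paste0("unknown ssd_age value(s): ",
                                    paste(bad, collapse = ", ")))

  offenders <- ann$gene_id[ann$ssd_age != "not_applicable" &
                             ann$dup_category != "SSD"]
  if (length(offenders) > 0) {
    abort(paste0("ssd_age set on non-SSD gene(s): ",
                 paste(head(offenders, 5), collapse = ", ")))
  }
  singles <- ann$status == "singleton"
  offenders <- ann$gene_id[singles &
                             (ann$dup_category != "none" | !is.na(ann$family_id))]
  if (length(offenders) > 0) {
    abort(paste0("singleton(s) with a duplication category or family: ",
                 paste(head(offenders, 5), collapse = ", ")))
  }
  fam <- ann[!is.na(ann$family_id), c("family_id", "family_total_size")]
  if (nrow(fam) > 0) {
    counts <- dplyr::count(fam, .data$family_id, name = "n_members")
    sizes <- dplyr::distinct(fam)
    if (nrow(sizes) != dplyr::n_distinct(fam$family_id)) {
      abort("family_total_size differs between members of the same family")
    }
    chk <- dplyr::left_join(sizes, counts, by = "family_id")
    bad <- chk$family_id[chk$family_total_size < chk$n_members]
    if (length(bad) > 0) {
      abort(paste0("family_total_size smaller than annotated member count: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  ann
}

#' Read a gene annotation table
#'
#' @param path TSV with the columns of [validate_annotation()]. Reports the
#'   per-category gene counts in a load-summary message.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- validate_annotation(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      family_id = readr::col_character(),
                      chrom = readr::col_character(),
                      .default = readr::col_guess()
                    ))
  )
  counts <- dplyr::count(ann, .data$dup_category, .data$ssd_age)
  inform(paste0(
    "annotation loaded: ", nrow(ann), " genes (",
    paste(sprintf("%s/%s=%d", counts$dup_category, counts$ssd_age, counts$n),
          collapse = ", "), ")"))
  ann
}

# write a result tibble as TSV with a provenance header; doubles at 6
# significant digits
.write_result <- function(tbl, path, config, stage) {
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], signif, digits = 6)
  hdr <- sprintf("# regiotau %s | stage=%s | seed=%d | config=%s",
                 as.character(utils::packageVersion("regiotau")), stage,
                 config$rng_seed, config_hash(config))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a result table written by the pipeline
#'
#' Skips the provenance header line the pipeline writes above each table.
#'
#' @param path Path to a pipeline output TSV.
#' @return A tibble.
#' @export
read_result <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
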