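# The 13 sampled CNS regions and their fixed merge into 7 anatomically
# non-overlapping territories. Region-specificity always operates at the
# 7-region level so that a gene specific to several close sub-regions
# (e.g. the two cerebellar samplings) is not artificially penalised.

.REGIONS_13 <- c(
  "amygdala", "anterior cingulate cortex", "caudate", "cerebellar hemisphere",
  "cerebellum", "cortex", "frontal cortex", "hippocampus", "hypothalamus",
  "nucleus accumbens", "putamen", "spinal cord", "substantia nigra"
)

.MERGE_13_TO_7 <- c(
  "cerebellum"                = "cerebellum",
  "cerebellar hemisphere"     = "cerebellum",
  "cortex"                    = "cortex",
  "frontal cortex"            = "cortex",
  "anterior cingulate cortex" = "cortex",
  "putamen"                   = "basal ganglia",
  "nucleus accumbens"         = "basal ganglia",
  "caudate"                   = "basal ganglia",
  "amygdala"                  = "amygdala-hippocampus",
  "hippocampus"               = "amygdala-hippocampus",
  "hypothalamus"              = "hypothalamus",
  "spinal cord"               = "spinal cord",
  "substantia nigra"          = "substantia nigra"
)

.REGIONS_7 <- sort(unique(unname(.MERGE_13_TO_7)))

#' Fixed merge map from the 13 sampled CNS regions to 7 territories
#'
#' Anatomically overlapping samplings are pooled: the two cerebellar regions
#' into `cerebellum`, the three cortical regions into `cortex`, the three
#' striatal regions into `basal ganglia`, amygdala with hippocampus; the
#' hypothalamus, spinal cord and substantia nigra map to themselves.
#'
#' @return A tibble with columns `region_13` and `region_7` (13 rows).
#' @export
#' @examples
#' region_merge_map()
region_merge_map <- function() {
  tibble::tibble(
    region_13 = names(.MERGE_13_TO_7),
    region_7 = unname(.MERGE_13_TO_7)
  )
}

#' Region name sets
#'
#' @return Character vectors of the 13 sampled region names, or the 7 merged
#'   territory names (in the fixed lexicographic order used for tie-breaking).
#' @export
regions_13 <- function() .REGIONS_13

#' @rdname regions_13
#' @export
regions_7 <- function() .REGIONS_7

# map a vector of region_13 labels to region_7
.to_region_7 <- function(region_13) {
  bad <- setdiff(unique(region_13), names(.MERGE_13_TO_7))
  if (length(bad) > 0) {
    abort(paste0("unknown region_13 label(s): ", paste(bad, collapse = ", ")))
  }
  unname(.MERGE_13_TO_7[region_13])
}
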