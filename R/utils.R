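# Internal helpers shared across modules.

CELL_TYPES <- c("ILC1", "ILC2", "ILC3", "Th1", "Th2", "Th17")

# fixed pairing map between innate and adaptive subsets
PAIRINGS <- list(
  type1 = c(ILC = "ILC1", Th = "Th1"),
  type2 = c(ILC = "ILC2", Th = "Th2"),
  type3 = c(ILC = "ILC3", Th = "Th17")
)

lineage_of <- function(cell_type) {
  ifelse(grepl("^ILC", cell_type), "ILC", "Th")
}

response_of <- function(cell_type) {
  unname(c(ILC1 = 1L, ILC2 = 2L, ILC3 = 3L,
           Th1 = 1L, Th2 = 2L, Th17 = 3L)[cell_type])
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Complete a sample manifest
#'
#' Fills in `lineage` and `response_type` columns from `cell_type` (they are
#' functions of it: ILC1/2/3 pair with Th1/Th2/Th17) and validates the cell
#' type vocabulary.
#'
#' @param manifest Data frame with at least `sample_id` and `cell_type`.
#' @return A tibble with `sample_id`, `cell_type`, `lineage`,
#'   `response_type` and any further columns passed through.
#' @export
complete_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  need <- setdiff(c("sample_id", "cell_type"), names(manifest))
  if (length(need) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(manifest$cell_type), CELL_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
  }
  manifest$lineage <- lineage_of(manifest$cell_type)
  manifest$response_type <- response_of(manifest$cell_type)
  manifest
}

# matrix layer bookkeeping -----------------------------------------------

expr_layer <- function(x) attr(x, "layer") %||% "counts"

set_layer <- function(x, layer) {
  attr(x, "layer") <- layer
  x
}

assert_samples_match <- function(mat, manifest, what = "matrix") {
  missing <- setdiff(manifest$sample_id, colnames(mat))
  if (length(missing) > 0) {
    abort(paste0(what, " lacks manifest sample(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  invisible(TRUE)
}

# row-wise sd without matrixStats
row_sds <- function(mat) {
  apply(mat, 1L, sd)
}

rle_tie_term <- function(v) {
  len <- rle(sort(v))$lengths
  sum(len^3 - len)
}
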