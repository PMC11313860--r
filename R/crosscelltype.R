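#' Depth normalization for cross-cell-type comparisons
#'
#' Expression and burst size are both affected by sequencing depth (depth
#' changes the capture yield, which rescales the eject rate). To compare
#' them across samples or cell types, each value is divided by its sample's
#' reads per cell and multiplied by the average reads per cell across the
#' cell types compared:
#' `normalized = value / reads_per_cell * avg_reads_across_types`.
#' Reads per cell is the post-QC mean total counts per cell of the sample.
#'
#' @param value Numeric vector of values to normalize (expression or burst
#'   size).
#' @param reads_per_cell Reads per cell of the sample each value came from
#'   (recycled).
#' @param avg_reads_across_types Mean reads per cell across all compared
#'   cell types.
#' @return Normalized values (linear in `value`).
#' @examples
#' normalize_value(10, 20000, 40000) # 20
#' @export
normalize_value <- function(value, reads_per_cell, avg_reads_across_types) {
  if (any(reads_per_cell <= 0) || any(avg_reads_across_types <= 0))
    stop("sequencing depths must be positive", call. = FALSE)
  value / reads_per_cell * avg_reads_across_types
}

#' Normalize a fit table across cell types
#'
#' Applies [normalize_value()] to the `expression` and `burst_size` columns
#' of a per-gene fit table, given a per-cell-type depth table; the reference
#' depth is the mean reads per cell across the listed cell types.
#'
#' @param fits A [fit_genes()] table with a `cell_type` column.
#' @param depth_table Data frame `cell_type`, `reads_per_cell`.
#' @return `fits` with added `expression_norm` and `burst_size_norm`
#'   columns.
#' @export
normalize_across_celltypes <- function(fits, depth_table) {
  stopifnot(all(c("cell_type", "reads_per_cell") %in% names(depth_table)))
  if (!"cell_type" %in% names(fits))
    stop("`fits` needs a `cell_type` column", call. = FALSE)
  avg <- mean(depth_table$reads_per_cell)
  depth <- depth_table$reads_per_cell[match(fits$cell_type,
                                            depth_table$cell_type)]
  if (anyNA(depth))
    stop("cell type(s) missing from `depth_table`", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(fits),
                expression_norm = normalize_value(.data$expression, depth, avg),
                burst_size_norm = normalize_value(.data$burst_size, depth, avg))
}
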