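#' Cell-level quality control of a raw count matrix
#'
#' First quality-control stage: removes low-quality cells, empty droplets,
#' doublets and dying cells by clipping the extreme tails of the per-cell
#' feature-count (genes detected) and total-count distributions, and
#' excluding cells with a high mitochondrial read fraction. A cell is
#' retained when both covariates lie inside the central `q` quantile band
#' (`[(1-q)/2, 1-(1-q)/2]`, inclusive) *and* its mitochondrial fraction is
#' below `mito_max`. The two covariate bands are intersected.
#'
#' @param counts Gene-by-cell integer matrix with gene rownames.
#' @param q Central coverage fraction retained per covariate (default 0.90).
#' @param mito_max Maximum mitochondrial fraction (default 0.05; typical
#'   range 0.05-0.075).
#' @param mito_pattern Regular expression identifying mitochondrial genes by
#'   name (default `"^MT-|^mt-"`); ignored when `mito_fraction` is given.
#' @param mito_fraction Optional per-cell mitochondrial fraction (e.g. the
#'   simulated covariate of a [simulate_dataset()] cohort).
#' @return A `cell_qc` list: `counts` (filtered matrix), `kept` (logical per
#'   input cell), and `report` — a tibble of removal counts per criterion.
#' @export
filter_cells <- function(counts, q = 0.90, mito_max = 0.05,
                         mito_pattern = "^MT-|^mt-", mito_fraction = NULL) {
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stop("`q` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(mito_max) || mito_max <= 0 || mito_max >= 1)
    stop("`mito_max` must be in (0, 1)", call. = FALSE)
  counts <- as.matrix(counts)
  total <- colSums(counts)
  features <- colSums(counts > 0)
  if (is.null(mito_fraction)) {
    mito_rows <- grepl(mito_pattern, rownames(counts) %||% character(0))
    mito_fraction <- if (any(mito_rows))
      colSums(counts[mito_rows, , drop = FALSE]) / pmax(total, 1)
    else rep(0, ncol(counts))
  }
  if (length(mito_fraction) != ncol(counts))
    stop("`mito_fraction` must have one value per cell", call. = FALSE)
  lo <- (1 - q) / 2
  band <- function(x) {
    b <- quantile(x, c(lo, 1 - lo), names = FALSE, type = 7)
    x >= b[1] & x <= b[2]
  }
  ok_total <- band(total)
  ok_features <- band(features)
  ok_mito <- mito_fraction < mito_max
  kept <- ok_total & ok_features & ok_mito
  if (!any(kept))
    stop("no cells pass the filters; loosen `q` or `mito_max`",
         call. = FALSE)
  report <- tibble::tibble(
    criterion = c("total_counts_band", "feature_counts_band",
                  "mito_fraction", "retained"),
    n_cells = c(sum(!ok_total), sum(!ok_features), sum(!ok_mito), sum(kept))
  )
  structure(list(counts = counts[, kept, drop = FALSE], kept = kept,
                 report = report),
            class = "cell_qc")
}

#' @export
print.cell_qc <- function(x, ...) {
  cat(sprintf("cell QC: retained %d of %d cells\n",
              sum(x$kept), length(x$kept)))
  print(x$report)
  invisible(x)
}

#' Gene-level quality control of inferred rates
#'
#' Second quality-control stage, applied to the per-gene fit table: a gene
#' passes when the relative posterior uncertainty (unscaled MAD divided by
#' the median) of `k_on`, `k_off`, `k_eject` *and* the burst size are each
#' strictly below `ratio_max` (default 0.75), and the expression (mean
#' observed counts per cell) is strictly above `expression_min` (default
#' 0.01). Only genes passing this filter should enter downstream analyses.
#'
#' @param fits A data frame as produced by [fit_genes()] (columns
#'   `k_on_median`, `k_on_mad`, ..., `burst_size`, `burst_size_mad`,
#'   `expression`).
#' @param ratio_max Threshold for every MAD/median ratio.
#' @param expression_min Threshold for expression.
#' @return The input with added columns `k_on_ratio`, `k_off_ratio`,
#'   `k_eject_ratio`, `burst_size_ratio` and logical `pass`.
#' @export
filter_genes <- function(fits, ratio_max = 0.75, expression_min = 0.01) {
  fits <- tibble::as_tibble(fits)
  need <- c("k_on_median", "k_on_mad", "k_off_median", "k_off_mad",
            "k_eject_median", "k_eject_mad", "burst_size", "burst_size_mad",
            "expression")
  missing_cols <- setdiff(need, names(fits))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dplyr::mutate(
    fits,
    k_on_ratio = .data$k_on_mad / .data$k_on_median,
    k_off_ratio = .data$k_off_mad / .data$k_off_median,
    k_eject_ratio = .data$k_eject_mad / .data$k_eject_median,
    burst_size_ratio = .data$burst_size_mad / .data$burst_size,
    pass = .data$k_on_ratio < ratio_max &
      .data$k_off_ratio < ratio_max &
      .data$k_eject_ratio < ratio_max &
      .data$burst_size_ratio < ratio_max &
      .data$expression > expression_min
  )
}
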