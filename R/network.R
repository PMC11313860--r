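#' Depth-normalize a count matrix for covariance analysis
#'
#' Converts each gene's count to the fraction of its cell's total counts,
#' rescales by a common per-cell depth target (the mean reads per cell of
#' the shallowest sample being compared, ~30,000 in typical 10x data), and
#' rounds to keep counts discrete. Cells with zero totals are an error (they
#' should have been removed by cell QC).
#'
#' @param counts Gene-by-cell matrix.
#' @param depth_scale Common reads-per-cell target (> 0).
#' @return Integer matrix of the same shape.
#' @export
depth_normalize <- function(counts, depth_scale = 30000) {
  if (!is.numeric(depth_scale) || depth_scale <= 0)
    stop("`depth_scale` must be positive", call. = FALSE)
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts; run cell QC first", call. = FALSE)
  out <- round(sweep(counts, 2, tot, `/`) * depth_scale)
  storage.mode(out) <- "integer"
  out
}

#' Gene pairs eligible for correlation analysis
#'
#' Unordered pairs of genes where both members are detected (count > 0) in
#' at least `detection_fraction` of the cells of *both* matrices being
#' compared.
#'
#' @param mat_a,mat_b Depth-normalized matrices sharing a gene universe
#'   (rownames).
#' @param detection_fraction Minimum detection fraction per gene per matrix
#'   (default 0.10).
#' @return A tibble with columns `gene_a`, `gene_b` (each unordered pair
#'   once, `gene_a` < `gene_b` alphabetically).
#' @export
eligible_pairs <- function(mat_a, mat_b, detection_fraction = 0.10) {
  if (!is.numeric(detection_fraction) || detection_fraction <= 0 ||
      detection_fraction >= 1)
    stop("`detection_fraction` must be in (0, 1)", call. = FALSE)
  genes <- intersect(rownames(mat_a), rownames(mat_b))
  det <- function(m) rowMeans(m[genes, , drop = FALSE] > 0)
  keep <- genes[det(mat_a) >= detection_fraction &
                  det(mat_b) >= detection_fraction]
  keep <- sort(keep)
  if (length(keep) < 2L)
    return(tibble::tibble(gene_a = character(0), gene_b = character(0)))
  idx <- utils::combn(keep, 2L)
  tibble::tibble(gene_a = idx[1, ], gene_b = idx[2, ])
}

# Spearman correlations (midrank ties) for a set of pairs in one matrix
pair_spearman <- function(mat, pairs) {
  genes <- union(pairs$gene_a, pairs$gene_b)
  r <- t(apply(mat[genes, , drop = FALSE], 1, rank)) # midranks
  rc <- stats::cor(t(r)) # Pearson on ranks == Spearman
  rho <- rc[cbind(match(pairs$gene_a, genes), match(pairs$gene_b, genes))]
  rho
}

#' Perturbation-induced shift of the gene-gene correlation network
#'
#' Quantifies how a perturbation reorganizes coexpression across single
#' cells: per eligible gene pair, the Spearman rank correlation is computed
#' in the control and perturbed samples and their difference
#' `delta_rho = rho_pert - rho_ctrl` is compared against the same quantity
#' from two replicate samples of the unperturbed condition (the technical /
#' biological noise floor). The spread of each `delta_rho` distribution is
#' summarized by its unscaled MAD, on the signed differences and on the
#' absolute differences. The detection filter is applied within each
#' compared sample pair independently, so the two comparisons may use
#' different pair sets (both are returned).
#'
#' @param ctrl,pert,rep1,rep2 Gene-by-cell count matrices (raw; they are
#'   depth-normalized internally with the shared `depth_scale`).
#' @param depth_scale Common reads-per-cell target (use the mean reads per
#'   cell of the shallowest of the four samples).
#' @param detection_fraction Minimum per-sample detection fraction.
#' @return A `corr_shift` list: `perturbation` and `replicate` pair tables
#'   (`gene_a`, `gene_b`, `rho_1`, `rho_2`, `delta_rho`) and `summary`, a
#'   tibble with one row per comparison (`n_pairs`, `mad_delta`,
#'   `mad_abs_delta`, `median_delta`).
#' @export
correlation_shift <- function(ctrl, pert, rep1, rep2, depth_scale = 30000,
                              detection_fraction = 0.10) {
  mats <- purrr::map(list(ctrl = ctrl, pert = pert, rep1 = rep1,
                          rep2 = rep2),
                     depth_normalize, depth_scale = depth_scale)
  one <- function(m1, m2) {
    pairs <- eligible_pairs(m1, m2, detection_fraction)
    if (nrow(pairs) < 2L)
      stop("fewer than 2 eligible gene pairs", call. = FALSE)
    pairs$rho_1 <- pair_spearman(m1, pairs)
    pairs$rho_2 <- pair_spearman(m2, pairs)
    pairs$delta_rho <- pairs$rho_2 - pairs$rho_1
    pairs
  }
  pert_tbl <- one(mats$ctrl, mats$pert)
  rep_tbl <- one(mats$rep1, mats$rep2)
  summ <- function(tbl, label) {
    tibble::tibble(comparison = label, n_pairs = nrow(tbl),
                   mad_delta = mad_raw(tbl$delta_rho),
                   mad_abs_delta = mad_raw(abs(tbl$delta_rho)),
                   median_delta = median(tbl$delta_rho))
  }
  structure(list(perturbation = pert_tbl, replicate = rep_tbl,
                 summary = dplyr::bind_rows(
                   summ(pert_tbl, "perturbation_vs_control"),
                   summ(rep_tbl, "replicate_vs_replicate"))),
            class = "corr_shift")
}

#' @export
print.corr_shift <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.corr_shift <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$perturbation, comparison = "perturbation"),
    dplyr::mutate(object$replicate, comparison = "replicate"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                   y = .data$delta_rho)) +
    ggplot2::geom_violin() +
    ggplot2::labs(y = expression(Delta * rho ~ "(Spearman)"), x = NULL)
}
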