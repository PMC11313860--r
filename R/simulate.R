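#' @noRd
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_burn_in <- function(spec, rates) {
  half_lives <- 10 * log(2) / rates$k_decay
  cycles <- if (length(rates$state_rates))
    10 / min(rates$state_rates) else 0
  max(half_lives, cycles)
}

#' Exact stochastic simulation of one allele
#'
#' Draws mRNA counts from a telegraph model by the Gillespie stochastic
#' simulation algorithm (an exact realization of the CME). Each cell is an
#' independent trajectory: the gene state is initialized from the stationary
#' distribution of the switching chain, the count from the rounded stationary
#' mean, and the system is evolved for `burn_in` minutes (by default the
#' larger of ten decay half-lives and ten cycles of the slowest switching
#' rate) before the count is recorded.
#'
#' @inheritParams steady_state
#' @param n_cells Number of independent draws.
#' @param burn_in Burn-in time in minutes before sampling.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Integer vector of length `n_cells` (single-allele counts).
#' @export
gillespie_cell <- function(spec, rates, n_cells = 1L, burn_in = NULL,
                           seed = NULL) {
  check_rates(spec, rates)
  burn_in <- burn_in %||% default_burn_in(spec, rates)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  sw <- switching_matrix(spec, rates)
  pi0 <- switching_stationary_cpp(if (spec$n_states == 1L)
    matrix(0, 1, 1) else sw)
  p_on <- pi0[spec$n_states]
  init_m <- as.integer(round(rates$k_eject * p_on / rates$k_decay))
  gillespie_counts_cpp(sw, rates$k_eject, rates$k_decay,
                       as.integer(n_cells), burn_in, init_m, pi0,
                       as.double(seed))
}

#' Simulate a synthetic single-cell cohort
#'
#' Generates a gene-by-cell integer count matrix from a table of true
#' two-state telegraph rates: for each gene, `n_alleles` independent
#' single-allele counts are drawn per cell from the exact CME steady state
#' (or by SSA), summed, and thinned binomially at the capture `yield`.
#' Per-cell technical covariates (a simulated mitochondrial fraction and the
#' realized totals) are attached so the cell-level quality control has
#' something to operate on.
#'
#' @param truth A data frame with columns `gene`, `k_on`, `k_off`, `k_eject`,
#'   `k_decay` (rates in 1/min) and optionally `n_alleles`.
#' @param n_cells Number of cells.
#' @param yield Capture probability applied by binomial thinning.
#' @param n_alleles Default allele count for genes without an `n_alleles`
#'   column.
#' @param seed Integer seed (reproducible output).
#' @param method `"exact"` draws from the solved steady state (default);
#'   `"ssa"` runs the Gillespie algorithm per allele.
#' @param mito_shape Two-parameter Beta shape for the simulated mitochondrial
#'   fraction (defaults give mean 2%).
#' @param condition Label stored with the cohort.
#' @return A `synthetic_cohort`: list with `counts` (gene x cell integer
#'   matrix), `truth` (tibble), `cells` (per-cell covariate tibble) and
#'   `condition`.
#' @export
simulate_dataset <- function(truth, n_cells, yield = 1, n_alleles = 2L,
                             seed = NULL, method = c("exact", "ssa"),
                             mito_shape = c(2, 98), condition = "control") {
  method <- match.arg(method)
  truth <- tibble::as_tibble(truth)
  need <- c("gene", "k_on", "k_off", "k_eject", "k_decay")
  if (!all(need %in% names(truth)))
    stop("`truth` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"n_alleles" %in% names(truth)) truth$n_alleles <- as.integer(n_alleles)
  with_preserved_seed(seed, {
    counts <- matrix(0L, nrow(truth), n_cells,
                     dimnames = list(truth$gene,
                                     sprintf("cell%05d", seq_len(n_cells))))
    for (i in seq_len(nrow(truth))) {
      spec_i <- telegraph_model(2L, n_alleles = truth$n_alleles[i],
                                yield = yield)
      r <- telegraph_rates(k_on = truth$k_on[i], k_off = truth$k_off[i],
                           k_eject = truth$k_eject[i],
                           k_decay = truth$k_decay[i])
      na <- truth$n_alleles[i]
      if (method == "exact") {
        d <- steady_state(spec_i, r)
        draw <- sample.int(length(d), n_cells * na, replace = TRUE,
                           prob = as.numeric(d)) - 1L
      } else {
        cseed <- (seed %||% 0L) + i * 7919L
        draw <- gillespie_cell(spec_i, r, n_cells = n_cells * na,
                               seed = cseed)
      }
      tot <- colSums(matrix(draw, nrow = na))
      if (yield < 1) tot <- rbinom(n_cells, size = tot, prob = yield)
      counts[i, ] <- as.integer(tot)
    }
    cells <- tibble::tibble(
      barcode = colnames(counts),
      total_counts = colSums(counts),
      feature_counts = colSums(counts > 0),
      mito_fraction = stats::rbeta(n_cells, mito_shape[1], mito_shape[2])
    )
    structure(list(counts = counts, truth = truth, cells = cells,
                   yield = yield, condition = condition),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort '%s': %d genes x %d cells\n",
              x$condition, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Induce rank correlation between gene pairs of a cohort
#'
#' Re-draws the counts of designated gene pairs through a Gaussian copula: a
#' latent bivariate normal with Pearson correlation `2 sin(pi * rho / 6)`
#' (so the latent Spearman correlation equals `rho`) is mapped through each
#' gene's model count distribution by inverse-CDF, which preserves the
#' marginal histogram exactly while coupling the per-cell ranks. Because
#' counts are discrete, the achieved Spearman correlation is attenuated for
#' weakly expressed genes; the achieved values are returned and a warning is
#' raised when they fall far from the target.
#'
#' @details Pairs may overlap: the pair graph is decomposed into connected
#' components and each component's genes share one latent factor, giving a
#' uniform latent correlation within the component (the mean of the
#' component's pair targets; negative targets are only feasible for isolated
#' two-gene components). Disjoint pairs reduce to independent bivariate
#' couplings.
#'
#' @param cohort A `synthetic_cohort` from [simulate_dataset()].
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param rho Target Spearman correlation(s) in (-1, 1), recycled over pairs.
#' @param seed Integer seed.
#' @return The cohort with re-drawn counts for the paired genes and a
#'   `pairs` tibble (with `rho_target`, `rho_achieved`) attached.
#' @export
simulate_correlated_pairs <- function(cohort, pairs, rho, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  rho <- rep_len(rho, nrow(pairs))
  if (any(abs(rho) >= 1)) stop("`rho` must lie in (-1, 1)", call. = FALSE)
  gs <- unique(c(pairs$gene_a, pairs$gene_b))
  if (!all(gs %in% rownames(cohort$counts)))
    stop("pair genes absent from the cohort", call. = FALSE)
  n_cells <- ncol(cohort$counts)
  truth <- cohort$truth
  cell_dist <- function(g) {
    i <- match(g, truth$gene)
    spec_i <- telegraph_model(2L, n_alleles = truth$n_alleles[i])
    r <- telegraph_rates(k_on = truth$k_on[i], k_off = truth$k_off[i],
                         k_eject = truth$k_eject[i],
                         k_decay = truth$k_decay[i])
    d <- convolve_alleles(steady_state(spec_i, r), truth$n_alleles[i])
    y <- cohort$yield %||% 1
    if (y < 1) d <- thin_distribution(d, y)
    d
  }
  # connected components of the pair graph (union-find)
  parent <- setNames(seq_along(gs), gs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(match(pairs$gene_a[k], gs))
    b <- find(match(pairs$gene_b[k], gs))
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(gs), find, integer(1))
  with_preserved_seed(seed, {
    for (cid in unique(comp)) {
      members <- gs[comp == cid]
      in_comp <- pairs$gene_a %in% members | pairs$gene_b %in% members
      rho_c <- mean(rho[in_comp])
      r_pearson <- 2 * sin(pi * rho_c / 6)
      if (length(members) == 2L) {
        z <- matrix(rnorm(2L * n_cells), ncol = 2L)
        z[, 2] <- r_pearson * z[, 1] + sqrt(1 - r_pearson^2) * z[, 2]
      } else {
        if (r_pearson < 0)
          stop("negative targets are infeasible for overlapping pairs",
               call. = FALSE)
        lam <- sqrt(r_pearson)
        w <- rnorm(n_cells)
        z <- lam * w +
          sqrt(1 - lam^2) * matrix(rnorm(length(members) * n_cells),
                                   ncol = length(members))
        z <- matrix(z, ncol = length(members))
      }
      for (j in seq_along(members)) {
        d <- cell_dist(members[j])
        cdf <- cumsum(as.numeric(d))
        cohort$counts[members[j], ] <-
          as.integer(findInterval(stats::pnorm(z[, j]), cdf))
      }
    }
    ach <- vapply(seq_len(nrow(pairs)), function(k) {
      r <- suppressWarnings(
        cor(cohort$counts[pairs$gene_a[k], ],
            cohort$counts[pairs$gene_b[k], ], method = "spearman"))
      if (is.na(r)) 0 else r
    }, numeric(1))
    pairs$rho_target <- rho
    pairs$rho_achieved <- ach
    off <- abs(ach - rho)
    if (any(off > 0.15))
      warning(sprintf(
        "achieved Spearman correlation off target by up to %.2f (discrete marginals)",
        max(off)), call. = FALSE)
    cohort$pairs <- pairs
    cohort
  })
}

#' Simulate an actinomycin-D decay time course
#'
#' Emulates a transcription-shutoff experiment: per-gene expression decays
#' exponentially from its baseline with gene-specific half-lives, observed
#' with multiplicative log-normal noise and per-sample library scale factors;
#' ERCC-style spike-in rows are present at known amounts and scale exactly
#' with each sample, so spike-in normalization can recover the scale factors.
#'
#' @param half_lives Named numeric vector of true half-lives in hours (names
#'   are gene ids), or a data frame with columns `gene`, `half_life_hours`.
#' @param timepoints Harvest times in hours; must start at 0 (default
#'   0, 1, 2, 4, 8, 12, 24).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise (0 gives noiseless exponentials).
#' @param baseline Optional named vector of expression at t = 0; drawn
#'   log-normally by default.
#' @param spikein_amounts Named vector of known spike-in input amounts; names
#'   must carry the spike-in prefix (default 16 "ERCC-" rows spanning a
#'   dilution series).
#' @param scale_factors Optional per-sample scale factors (default drawn
#'   log-normally with 20% CV, first sample fixed at 1).
#' @param seed Integer seed.
#' @return A `decay_sim` list: `counts` (genes + spike-ins by timepoints,
#'   continuous expression values), `timepoints`, `spikein_amounts`, `truth`
#'   tibble and `scale_factors`.
#' @export
simulate_decay_course <- function(half_lives,
                                  timepoints = c(0, 1, 2, 4, 8, 12, 24),
                                  noise_cv = 0.1, baseline = NULL,
                                  spikein_amounts = NULL,
                                  scale_factors = NULL, seed = NULL) {
  if (is.data.frame(half_lives))
    half_lives <- setNames(half_lives$half_life_hours, half_lives$gene)
  if (is.null(names(half_lives)))
    names(half_lives) <- sprintf("gene%03d", seq_along(half_lives))
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be strictly increasing from 0", call. = FALSE)
  with_preserved_seed(seed, {
    G <- length(half_lives)
    Tn <- length(timepoints)
    baseline <- baseline %||%
      setNames(rlnorm(G, meanlog = log(500), sdlog = 1), names(half_lives))
    spikein_amounts <- spikein_amounts %||%
      setNames(2^seq(3, 13, length.out = 16), sprintf("ERCC-%05d", 1:16))
    scale_factors <- scale_factors %||%
      c(1, rlnorm(Tn - 1, meanlog = 0, sdlog = sqrt(log(1 + 0.2^2))))
    k <- log(2) / half_lives
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    sample_names <- sprintf("t%g", timepoints)
    expr <- outer(seq_len(G), seq_len(Tn), function(i, j)
      baseline[i] * exp(-k[i] * timepoints[j]))
    if (sdlog > 0)
      expr <- expr * matrix(rlnorm(G * Tn, -sdlog^2 / 2, sdlog), G, Tn)
    expr <- sweep(expr, 2, scale_factors, `*`)
    spk <- outer(spikein_amounts, scale_factors)
    counts <- rbind(expr, spk)
    dimnames(counts) <- list(c(names(half_lives), names(spikein_amounts)),
                             sample_names)
    structure(list(
      counts = counts, timepoints = timepoints,
      spikein_amounts = spikein_amounts,
      truth = tibble::tibble(gene = names(half_lives),
                             half_life_hours = unname(half_lives),
                             baseline = unname(baseline)),
      scale_factors = setNames(scale_factors, sample_names)),
      class = "decay_sim")
  })
}
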