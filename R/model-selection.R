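#' Akaike information criterion
#'
#' `AIC = 2k - 2 logL` with `k` free parameters (the fixed decay rate is not
#' counted: 1 for the one-state model, 3 for the two-state, 5 for the
#' reversible three-state chain).
#'
#' @param max_loglik Maximized log likelihood.
#' @param k Number of free parameters (>= 1).
#' @return A single number; smaller is better.
#' @export
aic <- function(max_loglik, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  2 * k - 2 * max_loglik
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` computed from a matrix of pointwise log
#' likelihoods (posterior draws in rows, cells in columns):
#' `lppd = sum_c log mean_d exp(ll[d, c])` (evaluated by log-sum-exp) and
#' the effective parameter count `p_waic = sum_c var_d(ll[d, c])`.
#'
#' @param ll Numeric matrix, draws x cells.
#' @return A single number; smaller is better.
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) stop("at least 2 posterior draws are required",
                          call. = FALSE)
  lse <- apply(ll, 2, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  })
  lppd <- sum(lse)
  p_waic <- sum(apply(ll, 2, var))
  -2 * (lppd - p_waic)
}

#' Compare telegraph models of different sizes
#'
#' Given fits of the 1-, 2- and 3-state models to the same counts, computes
#' AIC (from the best log likelihood seen across posterior draws and the
#' optional MLE refinement) and WAIC (from the pointwise posterior log
#' likelihoods), and declares a winner per criterion. Ties are broken
#' towards the model with fewer states.
#'
#' @param fits A list of `burst_fit` objects (any subset of state counts,
#'   all fit to identical counts).
#' @return A `model_comparison` tibble with one row per model
#'   (`n_states`, `k`, `max_loglik`, `aic`, `waic`) and attributes
#'   `winner_aic` / `winner_waic` (number of states).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fitted models", call. = FALSE)
  counts0 <- fits[[1]]$counts
  for (f in fits) {
    if (!inherits(f, "burst_fit")) stop("missing fit", call. = FALSE)
    if (!identical(f$counts, counts0))
      stop("all fits must be on identical counts", call. = FALSE)
  }
  rows <- purrr::map(fits, function(f) {
    k <- n_free_rates(f$spec)
    best_ll <- max(unlist(f$chains$loglik))
    if (!is.null(f$mle)) best_ll <- max(best_ll, f$mle$logLik)
    w <- waic(pointwise_loglik(f$chains))
    tibble::tibble(n_states = f$spec$n_states, k = k, max_loglik = best_ll,
                   aic = aic(best_ll, k), waic = w)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$n_states)
  pick <- function(crit) {
    # ties towards parsimony: first minimum in increasing state order
    out$n_states[which.min(crit)]
  }
  attr(out, "winner_aic") <- pick(out$aic)
  attr(out, "winner_waic") <- pick(out$waic)
  class(out) <- c("model_comparison", class(out))
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("winner (AIC): %d-state | winner (WAIC): %d-state\n",
              attr(x, "winner_aic"), attr(x, "winner_waic")))
  invisible(x)
}

#' @rdname select_model
#' @param counts Per-cell counts of one gene.
#' @param k_decay Fixed decay rate (1/min).
#' @param states Which model sizes to fit (default 1:3).
#' @param n_alleles Allele count shared by all fits.
#' @param ... Passed to [fit_telegraph()].
#' @export
compare_states <- function(counts, k_decay, states = 1:3, n_alleles = 2L,
                           ...) {
  fits <- purrr::map(states, function(s)
    fit_telegraph(counts, k_decay = k_decay,
                  spec = telegraph_model(s, n_alleles = n_alleles),
                  mle = TRUE, ...))
  select_model(fits)
}
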