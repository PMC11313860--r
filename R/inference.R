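#' Log-normal priors on the free rates
#'
#' Broad log-normal priors for the free rates of a telegraph model, specified
#' by mean and coefficient of variation on the natural (rate) scale. The
#' defaults are means of 0.01 /min for the ON rate, 0.1 /min for the OFF
#' rate, 0.05 /min for the eject rate, and a CV of 10 for all three,
#' reflecting prior fits to live-cell data. In log space these translate to
#' `sigma^2 = log(1 + CV^2)` and `mu = log(mean) - sigma^2 / 2`. The decay
#' rate carries no prior: it is fixed at the measured `log(2) / half-life`
#' (optionally a narrow log-normal prior, see [run_mcmc()]).
#'
#' For three-state chains, the "up" transitions (towards ON) inherit the ON
#' rate prior and the "down" transitions the OFF rate prior.
#'
#' @param mean_on,mean_off,mean_eject Prior means in 1/min.
#' @param cv Coefficient of variation (shared).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(mean_on = 0.01, mean_off = 0.1, mean_eject = 0.05,
                       cv = 10) {
  stopifnot(mean_on > 0, mean_off > 0, mean_eject > 0, cv > 0)
  structure(list(mean_on = mean_on, mean_off = mean_off,
                 mean_eject = mean_eject, cv = cv),
            class = "prior_spec")
}

# log-space (mu, sigma) per free rate, in sampler order: switching then eject
prior_logspace <- function(prior, spec) {
  sigma <- sqrt(log(1 + prior$cv^2))
  mu_of <- function(mean) log(mean) - sigma^2 / 2
  means <- switch(spec$n_states,
    prior$mean_eject,
    c(prior$mean_on, prior$mean_off, prior$mean_eject),
    if (spec$topology == "cyclic")
      c(prior$mean_on, prior$mean_on, prior$mean_off, prior$mean_eject)
    else
      c(prior$mean_on, prior$mean_off, prior$mean_on, prior$mean_off,
        prior$mean_eject))
  list(mu = mu_of(means), sigma = rep(sigma, length(means)),
       names = c(switch_rate_names(spec), "k_eject"))
}

#' Log prior density of a rate set
#'
#' Sum of log-normal log-densities over the free rates (switching + eject);
#' the decay rate is fixed and contributes nothing.
#'
#' @param prior A [prior_spec()].
#' @param rates A [telegraph_rates()].
#' @param spec A [telegraph_model()] (defaults to the two-state model).
#' @return A single number; `-Inf` for non-positive rates.
#' @export
log_prior <- function(prior, rates, spec = telegraph_model(2L)) {
  free <- c(rates$state_rates, rates$k_eject)
  if (any(free <= 0)) return(-Inf)
  ls <- prior_logspace(prior, spec)
  sum(stats::dlnorm(free, meanlog = ls$mu, sdlog = ls$sigma, log = TRUE))
}

#' Log likelihood of counts under a count distribution
#'
#' Cells are independent, so the log likelihood is the sum of the log
#' predicted probability at each observed count — `n` times the negative
#' cross entropy between the empirical histogram and the model pmf.
#' Probabilities below 1e-300 (including counts beyond the truncation) are
#' floored with a warning.
#'
#' @param dist A `burst_dist` (per-cell distribution, i.e. already
#'   allele-convolved where relevant).
#' @param counts Non-negative integer vector of per-cell mRNA counts.
#' @return A single number.
#' @examples
#' log_likelihood(new_poisson_dist(2, 20), c(0, 1, 2))
#' @export
log_likelihood <- function(dist, counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("`counts` is empty", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  p <- as.numeric(dist)
  pc <- ifelse(counts + 1L <= length(p), p[pmin(counts + 1L, length(p))], 0)
  if (any(pc < 1e-300)) {
    warning("some observed counts have probability below the 1e-300 floor",
            call. = FALSE)
    pc <- pmax(pc, 1e-300)
  }
  sum(log(pc))
}

#' Poisson count distribution helper
#'
#' Truncated Poisson pmf as a `burst_dist`; the steady state of the one-state
#' model with `nu = lambda`.
#' @param lambda Mean.
#' @param truncation Cutoff.
#' @export
new_poisson_dist <- function(lambda, truncation) {
  new_burst_dist(dpois(0:truncation, lambda))
}

#' Sample rate posteriors by Metropolis-Hastings
#'
#' Adaptive random-scan Metropolis-Hastings over the log rates of a
#' telegraph model, with the decay rate fixed at `k_decay` and a log-normal
#' prior on each free rate. Each iteration perturbs one log rate with a
#' Gaussian step whose scale is tuned per parameter during warmup towards a
#' 20-40% acceptance rate; the first `warmup` fraction of samples is
#' discarded. The likelihood is evaluated through the truncated CME steady
#' state (allele-convolved), with the truncation re-chosen adaptively at
#' every proposal. Chains are reproducible bit-for-bit under a fixed seed.
#'
#' @param counts Integer vector of per-cell mRNA counts for one gene.
#' @param spec A [telegraph_model()].
#' @param prior A [prior_spec()].
#' @param k_decay Fixed decay rate in 1/min (`log(2) /` half-life in
#'   minutes).
#' @param n_chains Number of chains (2-8 supported; default 4).
#' @param n_samples Iterations per chain including warmup (default 50000).
#' @param seed Integer seed.
#' @param warmup Fraction of samples discarded as warmup (default 0.25).
#' @param min_cells With all-zero counts and fewer than this many cells the
#'   fit refuses to run ("insufficient data").
#' @param trunc_tol,trunc_cap Tail tolerance and hard cap for the adaptive
#'   CME truncation.
#' @param init_jitter Log-space standard deviation of the chain
#'   initialization around the prior log means (disperses chains for r-hat).
#' @return A `burst_chains` object: per-chain matrices of log-rate draws
#'   (post-warmup), per-draw log likelihoods, acceptance rates and fit
#'   metadata.
#' @export
run_mcmc <- function(counts, spec = telegraph_model(2L),
                     prior = prior_spec(), k_decay, n_chains = 4L,
                     n_samples = 50000L, seed = NULL, warmup = 0.25,
                     min_cells = 25L, trunc_tol = 1e-8, trunc_cap = 10000L,
                     init_jitter = 0.5) {
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("`counts` is empty", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  if (!is.numeric(k_decay) || k_decay <= 0)
    stop("`k_decay` must be positive (decay rate required)", call. = FALSE)
  if (all(counts == 0L) && length(counts) < min_cells)
    stop("insufficient data: all counts are zero in fewer than ",
         min_cells, " cells", call. = FALSE)
  n_chains <- as.integer(n_chains)
  if (n_chains < 1L || n_chains > 8L)
    stop("`n_chains` must be between 1 and 8", call. = FALSE)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  max_m <- max(counts)
  hist <- tabulate(counts + 1L, nbins = max_m + 1L)
  ls <- prior_logspace(prior, spec)
  idx <- switching_index(spec)
  n_warm <- as.integer(floor(n_samples * warmup))
  draws <- vector("list", n_chains)
  logliks <- vector("list", n_chains)
  acc <- numeric(n_chains)
  with_preserved_seed(seed, {
    for (ch in seq_len(n_chains)) {
      theta0 <- ls$mu + init_jitter * rnorm(length(ls$mu))
      res <- mh_chain_cpp(hist, spec$n_states, spec$n_alleles,
                          idx$from, idx$to, k_decay, ls$mu, ls$sigma,
                          theta0, as.integer(n_samples), n_warm,
                          scale_init = 0.5, trunc_tol = trunc_tol,
                          trunc_cap = as.integer(trunc_cap),
                          seed = as.double(seed) * 16L + ch)
      colnames(res$draws) <- ls$names
      draws[[ch]] <- res$draws
      logliks[[ch]] <- res$loglik
      acc[ch] <- res$acceptance
    }
  })
  structure(list(draws = draws, loglik = logliks, acceptance = acc,
                 spec = spec, prior = prior, k_decay = k_decay,
                 n_samples = n_samples, n_warmup = n_warm, seed = seed,
                 param_names = ls$names, counts_hist = hist,
                 n_cells = length(counts), max_count = max_m),
            class = "burst_chains")
}

#' @export
print.burst_chains <- function(x, ...) {
  cat(sprintf(
    "MCMC draws: %d chain(s) x %d kept samples over %d free rate(s)\n",
    length(x$draws), nrow(x$draws[[1]]), length(x$param_names)))
  cat(sprintf("acceptance: %s\n",
              paste(sprintf("%.2f", x$acceptance), collapse = ", ")))
  invisible(x)
}

# pooled post-warmup draws as one matrix
pooled_draws <- function(chains) {
  do.call(rbind, chains$draws)
}

#' Potential scale reduction factor (r-hat)
#'
#' Gelman-Rubin convergence diagnostic comparing between- and within-chain
#' variance; values near 1 indicate convergence. By default each chain is
#' split in half (split r-hat), which also detects non-stationarity within a
#' chain.
#'
#' @param chains A `burst_chains` object, or a numeric matrix with one
#'   column per chain.
#' @param parameter Parameter name or index (for `burst_chains`).
#' @param split Split each chain in half first (default `TRUE`).
#' @return A single number >= (approximately) 1. Zero within-chain variance
#'   returns 1 with a warning.
#' @export
rhat <- function(chains, parameter = 1L, split = TRUE) {
  mat <- if (inherits(chains, "burst_chains")) {
    if (is.character(parameter))
      parameter <- match(parameter, chains$param_names)
    vapply(chains$draws, function(d) d[, parameter], numeric(nrow(chains$draws[[1]])))
  } else {
    as.matrix(chains)
  }
  if (ncol(mat) < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (nrow(mat) < 4L) stop("each chain needs at least 4 draws", call. = FALSE)
  if (split) {
    half <- floor(nrow(mat) / 2)
    mat <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[nrow(mat) - half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(mat); m <- ncol(mat)
  W <- mean(apply(mat, 2, var))
  if (W == 0) {
    warning("zero within-chain variance; r-hat defined as 1", call. = FALSE)
    return(1)
  }
  B <- n * var(colMeans(mat))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior draws
#'
#' Pools the post-warmup draws of all chains and reports, for each free rate
#' and for the derived OFF time (`1/k_on`) and burst size (`k_eject/k_off`),
#' the posterior median, the unscaled MAD, and the central 95% credible
#' interval. Derived quantities are computed per draw from the joint
#' posterior, so burst-size uncertainty propagates the cross-correlation
#' between the OFF and eject rates. Split r-hat is attached per free rate.
#'
#' @param chains A `burst_chains` object.
#' @param counts Optional original counts; if supplied, the summary records
#'   the expression (mean count per cell) and the log likelihood at the
#'   posterior median.
#' @param yield Optional capture probability; when < 1 the eject-rate draws
#'   (and hence burst size) are divided by it for reporting, undoing the
#'   technical rescaling `nu -> p * nu`.
#' @return A `burst_summary` tibble (parameter, median, mad, ci_lower,
#'   ci_upper, rhat) with fit-level metadata in attributes.
#' @export
summarize_posterior <- function(chains, counts = NULL, yield = 1) {
  stopifnot(inherits(chains, "burst_chains"))
  pool <- exp(pooled_draws(chains)) # draws on the rate scale
  if (yield < 1) pool[, "k_eject"] <- pool[, "k_eject"] / yield
  spec <- chains$spec
  derived <- list()
  if (spec$n_states >= 2L) {
    k_on_col <- 1L
    k_off_col <- n_switch_rates(spec) # last "down" rate (k_off or r32)
    if (spec$n_states == 2L)
      derived$off_time <- 1 / pool[, k_on_col]
    derived$burst_size <- pool[, "k_eject"] / pool[, k_off_col]
  }
  all_draws <- cbind(pool, do.call(cbind, derived))
  qs <- apply(all_draws, 2, quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  rh <- if (length(chains$draws) >= 2L && nrow(chains$draws[[1]]) >= 4L)
    vapply(seq_along(chains$param_names), function(j) rhat(chains, j),
           numeric(1))
  else rep(NA_real_, length(chains$param_names))
  out <- tibble::tibble(
    parameter = colnames(all_draws),
    median = unname(qs[2, ]),
    mad = unname(apply(all_draws, 2, mad_raw)),
    ci_lower = unname(qs[1, ]),
    ci_upper = unname(qs[3, ]),
    rhat = c(rh, rep(NA_real_, ncol(all_draws) - length(rh)))
  )
  med_theta <- apply(pooled_draws(chains), 2, median)
  attr(out, "loglik_median") <- loglik_at(chains, med_theta)
  attr(out, "expression") <- if (!is.null(counts)) {
    mean(counts)
  } else {
    h <- chains$counts_hist
    sum((seq_along(h) - 1L) * h) / sum(h)
  }
  attr(out, "n_cells") <- chains$n_cells
  attr(out, "acceptance") <- mean(chains$acceptance)
  attr(out, "rhat_max") <- max(rh)
  attr(out, "model_states") <- spec$n_states
  class(out) <- c("burst_summary", class(out))
  out
}

# log likelihood of the observed histogram at a log-rate vector
loglik_at <- function(chains, theta) {
  spec <- chains$spec
  idx <- switching_index(spec)
  lpm <- logprob_matrix_cpp(matrix(theta, nrow = 1), spec$n_states,
                            spec$n_alleles, idx$from, idx$to,
                            chains$k_decay, chains$max_count, 1e-8, 10000L)
  sum(chains$counts_hist * lpm[1, ])
}

# per-draw log likelihoods recomputed on a thinned set of pooled draws,
# expanded per cell: rows = draws, cols = cells (for WAIC)
pointwise_loglik <- function(chains, max_draws = 200L) {
  pool <- pooled_draws(chains)
  keep <- unique(round(seq(1L, nrow(pool), length.out = min(max_draws,
                                                            nrow(pool)))))
  spec <- chains$spec
  idx <- switching_index(spec)
  lpm <- logprob_matrix_cpp(pool[keep, , drop = FALSE], spec$n_states,
                            spec$n_alleles, idx$from, idx$to, chains$k_decay,
                            chains$max_count, 1e-8, 10000L)
  cells <- rep(seq_along(chains$counts_hist), chains$counts_hist)
  lpm[, cells, drop = FALSE]
}

#' Maximum likelihood rate estimates
#'
#' Multi-start bounded optimization of the log likelihood over the log
#' rates, as a frequentist comparison to the posterior medians. Starts at
#' the prior log means plus jitter; the best optimum across starts is
#' returned.
#'
#' @inheritParams run_mcmc
#' @param starts Number of optimizer starts.
#' @return A list with `rates` (a [telegraph_rates()]), `logLik`, the
#'   optimized log-rate vector `theta`, and `convergence` (0 = success for
#'   at least one start).
#' @export
mle_fit <- function(counts, spec = telegraph_model(2L), k_decay,
                    prior = prior_spec(), starts = 5L, seed = NULL,
                    trunc_tol = 1e-8, trunc_cap = 10000L) {
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("`counts` is empty", call. = FALSE)
  max_m <- max(counts)
  hist <- tabulate(counts + 1L, nbins = max_m + 1L)
  ls <- prior_logspace(prior, spec)
  idx <- switching_index(spec)
  negll <- function(theta) {
    if (any(theta < -30) || any(theta > 12)) return(1e12)
    lpm <- try(logprob_matrix_cpp(matrix(theta, nrow = 1), spec$n_states,
                                  spec$n_alleles, idx$from, idx$to, k_decay,
                                  max_m, trunc_tol, as.integer(trunc_cap)),
               silent = TRUE)
    if (inherits(lpm, "try-error")) return(1e12)
    -sum(hist * lpm[1, ])
  }
  best <- NULL
  with_preserved_seed(seed, {
    for (s in seq_len(starts)) {
      theta0 <- if (s == 1L) ls$mu else ls$mu + rnorm(length(ls$mu), sd = 1)
      fit <- try(
        if (length(theta0) == 1L) {
          o <- optim(theta0, negll, method = "Brent", lower = -30, upper = 12,
                     control = list(reltol = 1e-12))
          o
        } else {
          optim(theta0, negll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
        }, silent = TRUE)
      if (inherits(fit, "try-error") || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best))
    stop("MLE optimization failed to converge from all starts", call. = FALSE)
  theta <- setNames(best$par, ls$names)
  n_sw <- n_switch_rates(spec)
  rates <- telegraph_rates(state_rates = exp(theta[seq_len(n_sw)]),
                           k_eject = exp(theta[[n_sw + 1L]]),
                           k_decay = k_decay)
  list(rates = rates, logLik = -best$value, theta = theta,
       convergence = best$convergence)
}
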