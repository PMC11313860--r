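# shared fixture builders; everything is generated in code at test time

two_state <- function(n_alleles = 1L) telegraph_model(2L, n_alleles = n_alleles)

rates_2s <- function(k_on = 0.01, k_off = 0.1, k_eject = 0.5,
                     k_decay = 0.005) {
  telegraph_rates(k_on = k_on, k_off = k_off, k_eject = k_eject,
                  k_decay = k_decay)
}

rates_1s <- function(k_eject, k_decay = 1) {
  telegraph_rates(state_rates = numeric(0), k_eject = k_eject,
                  k_decay = k_decay)
}

rates_3s <- function(state_rates = c(0.01, 0.02, 0.05, 0.1), k_eject = 0.5,
                     k_decay = 0.005) {
  telegraph_rates(state_rates = state_rates, k_eject = k_eject,
                  k_decay = k_decay)
}

# truth table of plausible two-state rates for synthetic cohorts
make_truth <- function(n, seed = 1, k_decay = log(2) / (60 * 4)) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("g%03d", seq_len(n)),
    k_on = stats::rlnorm(n, log(0.01), 0.5),
    k_off = stats::rlnorm(n, log(0.05), 0.5),
    k_eject = stats::rlnorm(n, log(0.4), 0.4),
    k_decay = k_decay
  ))
}

# total-variation distance between an empirical count vector and a pmf
tv_distance <- function(counts, dist) {
  p <- as.numeric(dist)
  nb <- max(length(p), max(counts) + 1L)
  emp <- tabulate(counts + 1L, nbins = nb) / length(counts)
  p <- c(p, rep(0, nb - length(p)))
  0.5 * sum(abs(emp - p))
}

# draws true rates from the package's default log-normal priors, with a
# detectability rule:
# redraw genes whose expected per-cell mean count falls outside [lo, hi]
# or whose burst size exceeds burst_cap (such genes fail the expression /
# rate QC anyway and are not identifiable at cohort scale)
draw_prior_truth <- function(n, seed, half_life_hours = 4, n_alleles = 2L,
                             lo = 0.5, hi = 100, burst_cap = 300) {
  k_decay <- log(2) / (60 * half_life_hours)
  sigma <- sqrt(log(1 + 10^2))
  mu <- function(m) log(m) - sigma^2 / 2
  withr::with_seed(seed, {
    out <- vector("list", n)
    i <- 0L
    while (i < n) {
      k_on <- stats::rlnorm(1, mu(0.01), sigma)
      k_off <- stats::rlnorm(1, mu(0.1), sigma)
      k_eject <- stats::rlnorm(1, mu(0.05), sigma)
      mean_cell <- n_alleles * k_eject * (k_on / (k_on + k_off)) / k_decay
      if (mean_cell < lo || mean_cell > hi || k_eject / k_off > burst_cap)
        next
      i <- i + 1L
      out[[i]] <- tibble::tibble(gene = sprintf("g%03d", i), k_on = k_on,
                                 k_off = k_off, k_eject = k_eject,
                                 k_decay = k_decay,
                                 n_alleles = n_alleles)
    }
    dplyr::bind_rows(out)
  })
}

# minimal forged chain set, for summary/selection unit tests
forge_chains <- function(draw_list, counts, spec = telegraph_model(2L),
                         k_decay = 0.005, logliks = NULL) {
  max_m <- max(counts)
  structure(list(
    draws = draw_list,
    loglik = logliks %||% lapply(draw_list, function(d) rep(0, nrow(d))),
    acceptance = rep(0.3, length(draw_list)),
    spec = spec, prior = prior_spec(), k_decay = k_decay,
    n_samples = nrow(draw_list[[1]]), n_warmup = 0L, seed = 1L,
    param_names = colnames(draw_list[[1]]),
    counts_hist = tabulate(counts + 1L, nbins = max_m + 1L),
    n_cells = length(counts), max_count = max_m
  ), class = "burst_chains")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
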