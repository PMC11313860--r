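#' Fit a telegraph model to one gene's counts
#'
#' High-level wrapper: runs the Metropolis-Hastings sampler
#' ([run_mcmc()]), monitors convergence by split r-hat, reruns with a
#' doubled sample budget when any free rate has r-hat at or above
#' `rhat_limit`, and summarizes the posterior. Optionally refines a maximum
#' likelihood estimate for comparison.
#'
#' @inheritParams run_mcmc
#' @param half_life_hours mRNA half-life in hours; converted to the fixed
#'   decay rate `log(2) / (60 * half_life_hours)` per minute. Give either
#'   this or `k_decay`.
#' @param rhat_limit Rerun threshold on the maximum split r-hat (default
#'   1.05).
#' @param max_reruns Maximum number of doubled-budget reruns (default 1).
#' @param yield Optional capture probability used for reporting (divides the
#'   eject-rate posterior; see [summarize_posterior()]).
#' @param mle Also compute a multi-start MLE (default `FALSE`).
#' @return A `burst_fit` object with elements `chains`, `summary`, `mle`
#'   (or `NULL`), and the call metadata. Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect it.
#' @examples
#' \donttest{
#' spec <- telegraph_model(2, n_alleles = 1)
#' r <- telegraph_rates(k_on = 0.02, k_off = 0.1, k_eject = 0.4,
#'                      k_decay = 0.005)
#' x <- sample(0:40, 400, replace = TRUE,
#'             prob = as.numeric(steady_state(spec, r, truncation = 40)))
#' fit <- fit_telegraph(x, k_decay = 0.005, spec = spec,
#'                      n_samples = 4000, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_telegraph <- function(counts, half_life_hours = NULL, k_decay = NULL,
                          spec = telegraph_model(2L), prior = prior_spec(),
                          n_chains = 4L, n_samples = 50000L, seed = NULL,
                          rhat_limit = 1.05, max_reruns = 1L, yield = 1,
                          mle = FALSE, ...) {
  if (is.null(k_decay)) {
    if (is.null(half_life_hours))
      stop("decay rate required: give `half_life_hours` or `k_decay`",
           call. = FALSE)
    k_decay <- log(2) / (60 * half_life_hours)
  }
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  budget <- n_samples
  reruns <- 0L
  repeat {
    chains <- run_mcmc(counts, spec = spec, prior = prior, k_decay = k_decay,
                       n_chains = n_chains, n_samples = budget,
                       seed = seed + reruns, ...)
    smry <- summarize_posterior(chains, counts = counts, yield = yield)
    rh <- attr(smry, "rhat_max")
    if (is.na(rh) || rh < rhat_limit || reruns >= max_reruns) break
    reruns <- reruns + 1L
    budget <- budget * 2L
  }
  mle_res <- if (mle)
    mle_fit(counts, spec = spec, k_decay = k_decay, prior = prior,
            seed = seed) else NULL
  structure(list(chains = chains, summary = smry, mle = mle_res,
                 spec = spec, k_decay = k_decay, counts = as.integer(counts),
                 reruns = reruns, seed = seed),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("telegraph fit (%d-state, %d alleles) to %d cells\n",
              x$spec$n_states, x$spec$n_alleles, length(x$counts)))
  print(tibble::as_tibble(x$summary))
  invisible(x)
}

#' @rdname fit_telegraph
#' @param x A `burst_fit`.
#' @export
tidy.burst_fit <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' @rdname fit_telegraph
#' @export
glance.burst_fit <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_cells = attr(s, "n_cells"),
    expression = attr(s, "expression"),
    loglik = attr(s, "loglik_median"),
    rhat_max = attr(s, "rhat_max"),
    acceptance = attr(s, "acceptance"),
    model_states = attr(s, "model_states"),
    reruns = x$reruns
  )
}

#' @rdname fit_telegraph
#' @param object A `burst_fit`.
#' @export
autoplot.burst_fit <- function(object, ...) {
  counts <- object$counts
  max_m <- max(counts)
  emp <- tabulate(counts + 1L, nbins = max_m + 1L) / length(counts)
  med <- apply(pooled_draws(object$chains), 2, median)
  idx <- switching_index(object$spec)
  lpm <- logprob_matrix_cpp(matrix(med, nrow = 1), object$spec$n_states,
                            object$spec$n_alleles, idx$from, idx$to,
                            object$k_decay, max_m, 1e-8, 10000L)
  df <- tibble::tibble(count = rep(0:max_m, 2),
                       probability = c(emp, exp(lpm[1, ])),
                       which = rep(c("observed", "fitted"),
                                   each = max_m + 1L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$probability,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge", width = 0.8) +
    ggplot2::labs(x = "mRNA count per cell", y = "probability", fill = NULL)
}

#' Fit telegraph models gene by gene across a count matrix
#'
#' Applies [fit_telegraph()] to every row of a gene-by-cell count matrix,
#' using per-gene decay rates from a half-life table, and returns one tidy
#' row per gene with posterior medians, unscaled MADs, 95% credible bounds,
#' the derived OFF time and burst size, convergence and likelihood
#' diagnostics, and log10-scale copies of the rate medians.
#'
#' @param counts Gene-by-cell integer matrix with gene rownames (dense or
#'   sparse).
#' @param half_lives Data frame with columns `gene` and `half_life_hours`,
#'   or a named numeric vector of half-lives in hours.
#' @param alleles Optional data frame `gene`, `n_alleles` overriding the
#'   default allele count per gene.
#' @param n_states,n_alleles Model size and default allele count.
#' @param seed Master seed; gene `i` uses `seed + i` (keep `seed` modest so
#'   derived seeds stay below 2^31).
#' @param progress Print one line per gene.
#' @inheritParams fit_telegraph
#' @param ... Passed to [fit_telegraph()].
#' @return A tibble with one row per fitted gene; genes whose fit fails
#'   (e.g. insufficient data) are reported with `error` set and NA
#'   estimates.
#' @export
fit_genes <- function(counts, half_lives, alleles = NULL, n_states = 2L,
                      n_alleles = 2L, n_chains = 4L, n_samples = 50000L,
                      seed = 1L, yield = 1, progress = FALSE, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.data.frame(half_lives))
    half_lives <- setNames(half_lives$half_life_hours, half_lives$gene)
  allele_of <- function(g) {
    if (!is.null(alleles) && g %in% alleles$gene)
      as.integer(alleles$n_alleles[match(g, alleles$gene)])
    else as.integer(n_alleles)
  }
  rows <- purrr::map(seq_len(nrow(counts)), function(i) {
    g <- rownames(counts)[i]
    hl <- unname(half_lives[g])
    if (is.na(hl))
      return(tibble::tibble(gene = g, error = "no half-life"))
    if (progress) message("fitting ", g)
    spec <- telegraph_model(n_states, n_alleles = allele_of(g))
    fit <- tryCatch(
      fit_telegraph(counts[i, ], half_life_hours = hl, spec = spec,
                    n_chains = n_chains, n_samples = n_samples,
                    seed = seed + i, yield = yield, ...),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(tibble::tibble(gene = g, error = conditionMessage(fit)))
    s <- tidy(fit)
    grab <- function(param, col) {
      v <- s[[col]][match(param, s$parameter)]
      if (length(v) == 0L) NA_real_ else v
    }
    tibble::tibble(
      gene = g,
      n_cells = attr(fit$summary, "n_cells"),
      expression = attr(fit$summary, "expression"),
      k_on_median = grab("k_on", "median"),
      k_on_mad = grab("k_on", "mad"),
      k_on_lo = grab("k_on", "ci_lower"),
      k_on_hi = grab("k_on", "ci_upper"),
      k_off_median = grab("k_off", "median"),
      k_off_mad = grab("k_off", "mad"),
      k_off_lo = grab("k_off", "ci_lower"),
      k_off_hi = grab("k_off", "ci_upper"),
      k_eject_median = grab("k_eject", "median"),
      k_eject_mad = grab("k_eject", "mad"),
      k_eject_lo = grab("k_eject", "ci_lower"),
      k_eject_hi = grab("k_eject", "ci_upper"),
      off_time_min = grab("off_time", "median"),
      burst_size = grab("burst_size", "median"),
      burst_size_mad = grab("burst_size", "mad"),
      log10_k_on = log10(k_on_median),
      log10_k_off = log10(k_off_median),
      log10_k_eject = log10(k_eject_median),
      rhat_max = attr(fit$summary, "rhat_max"),
      loglik = attr(fit$summary, "loglik_median"),
      model_states = n_states,
      error = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}
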