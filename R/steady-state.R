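#' Steady-state mRNA count distribution of a telegraph model
#'
#' Solves the chemical master equation (CME) of the joint (gene state, mRNA
#' count) process at stationarity. The countably infinite system is truncated
#' at a count `N` chosen adaptively so that the probability mass at the
#' boundary is below `tol` (the distribution is concentrated at low counts),
#' and the stationary vector is the one-dimensional null space of the
#' truncated transition-rate matrix. The marginal over gene states is
#' returned.
#'
#' Two routes are provided. `method = "recursion"` (default) eliminates the
#' block-tridiagonal structure over mRNA levels in compiled code, reducing the
#' null-space computation to the final `n_states x n_states` block; it is the
#' fast path used inside the samplers. `method = "nullspace"` forms the dense
#' transposed generator and extracts its null space by QR/SVD, rejecting
#' degenerate problems whose two smallest singular values are not separated
#' by a factor of 1e6; it is the independent slow route used for
#' cross-checks.
#'
#' @param spec A [telegraph_model()]. The returned distribution is for a
#'   single allele; see [convolve_alleles()] for the per-cell distribution.
#' @param rates A [telegraph_rates()] object matching `spec`.
#' @param truncation Optional fixed count cutoff `N`; by default the cutoff
#'   starts from a moment-based estimate (at least `min_truncation`) and is
#'   doubled until the tail mass beyond `N - 1` is below `tol`.
#' @param tol Tail-mass tolerance (default 1e-8).
#' @param cap Hard cap on the truncation (default 10000); exceeding it raises
#'   a "distribution not concentrated" error.
#' @param min_truncation Lower bound for the adaptive cutoff, e.g. the
#'   largest observed count plus a margin.
#' @param method `"recursion"` or `"nullspace"` (see Details).
#'
#' @return A `burst_dist`: a probability vector over counts `0..N` (named by
#'   count) with attribute `truncation = N`, summing to 1.
#' @examples
#' spec <- telegraph_model(2, n_alleles = 1)
#' r <- telegraph_rates(k_on = 0.01, k_off = 0.1, k_eject = 0.5, k_decay = 0.005)
#' d <- steady_state(spec, r)
#' sum(d)
#' @export
steady_state <- function(spec, rates, truncation = NULL, tol = 1e-8,
                         cap = 10000L, min_truncation = 8L,
                         method = c("recursion", "nullspace")) {
  method <- match.arg(method)
  check_rates(spec, rates)
  sw <- switching_matrix(spec, rates)
  nu <- rates$k_eject
  kd <- rates$k_decay
  if (!is.null(truncation)) {
    truncation <- as.integer(truncation)
    probs <- if (method == "recursion") {
      cme_steady_state_cpp(sw, nu, kd, truncation)
    } else {
      nullspace_steady(spec, rates, truncation)
    }
    return(new_burst_dist(probs))
  }
  if (method == "recursion") {
    res <- cme_steady_adaptive_cpp(sw, nu, kd, as.integer(min_truncation),
                                   tol, as.integer(cap))
    return(new_burst_dist(res$probs))
  }
  # adaptive loop for the QR null-space route
  if (nu <= 0) return(new_burst_dist(c(1, rep(0, max(min_truncation, 1L)))))
  N <- max(min_truncation, 8L)
  repeat {
    probs <- nullspace_steady(spec, rates, N)
    if (probs[N + 1L] + probs[N] < tol) return(new_burst_dist(probs))
    if (N >= cap)
      stop("distribution not concentrated below the truncation cap",
           call. = FALSE)
    N <- min(2L * N, as.integer(cap))
  }
}

# dense QR/SVD null-space route on the transposed generator
nullspace_steady <- function(spec, rates, N) {
  G <- as.matrix(build_generator(spec, rates, truncation = N))
  A <- t(G)
  sv <- svd(A)
  n <- ncol(A)
  if (sv$d[n - 1L] < 1e6 * max(sv$d[n], .Machine$double.xmin * 1e6))
    stop("degenerate null space: two near-zero singular values", call. = FALSE)
  v <- sv$v[, n]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  S <- spec$n_states
  marg <- rowsum(v, rep(0:N, each = S))[, 1L]
  unname(marg / sum(marg))
}

new_burst_dist <- function(probs) {
  probs <- pmax(as.numeric(probs), 0)
  probs <- probs / sum(probs)
  names(probs) <- seq_along(probs) - 1L
  structure(probs, truncation = length(probs) - 1L, class = "burst_dist")
}

#' @export
print.burst_dist <- function(x, ...) {
  cat(sprintf("steady-state mRNA distribution over counts 0..%d (mean %.3f)\n",
              attr(x, "truncation"), sum(as.numeric(names(x)) * x)))
  invisible(x)
}

#' @export
autoplot.burst_dist <- function(object, ...) {
  df <- tibble::tibble(count = as.integer(names(object)),
                       probability = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$probability)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "mRNA count", y = "probability")
}

#' Transition-rate matrix of the truncated CME
#'
#' Builds the sparse generator of the joint (gene state, mRNA count) Markov
#' process, truncated at count `N`. States are ordered count-major (all gene
#' states of count 0, then count 1, ...). Entry `(i, j)` holds the rate of
#' the transition `i -> j`; the diagonal carries minus the total exit rate so
#' every row sums to zero (probability conservation). Ejection out of the
#' boundary level `N` is dropped so the truncated chain remains conservative.
#'
#' @inheritParams steady_state
#' @param truncation Count cutoff `N` (the matrix has
#'   `n_states * (N + 1)` rows).
#' @return A sparse `dgCMatrix`.
#' @export
build_generator <- function(spec, rates, truncation) {
  check_rates(spec, rates)
  S <- spec$n_states
  N <- as.integer(truncation)
  if (is.na(N) || N < 1L) stop("`truncation` must be a positive integer",
                               call. = FALSE)
  sw <- switching_matrix(spec, rates)
  nu <- rates$k_eject
  kd <- rates$k_decay
  idx <- function(m, g) m * S + g # 1-based with g in 1..S
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (m in 0:N) {
    for (g in seq_len(S)) {
      from <- idx(m, g)
      for (h in seq_len(S)) {
        if (h != g && sw[g, h] > 0) add(from, idx(m, h), sw[g, h])
      }
      if (g == S && m < N && nu > 0) add(from, idx(m + 1L, g), nu)
      if (m > 0) add(from, idx(m - 1L, g), m * kd)
    }
  }
  n <- S * (N + 1L)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(G) <- -Matrix::rowSums(G)
  methods::as(G, "CsparseMatrix")
}

#' Beta-Poisson probability mass function
#'
#' Closed-form steady state of the two-state telegraph model: a Poisson
#' distribution whose intensity `nu * lambda` is mixed over
#' `lambda ~ Beta(alpha, beta)`, where `alpha = k_on/k_decay`,
#' `beta = k_off/k_decay` and `nu = k_eject/k_decay`. Evaluated by adaptive
#' quadrature of the mixing integral in log space (the integrand is split at
#' its mode to keep sharply peaked cases accurate). Serves as the independent
#' oracle for the CME solver.
#'
#' @param alpha,beta Positive shape parameters (scaled ON/OFF switching
#'   rates).
#' @param nu Scaled ejection rate, >= 0.
#' @param n Vector of counts at which to evaluate the pmf.
#' @return Probabilities, one per element of `n`.
#' @examples
#' beta_poisson_pmf(1, 1, 10, 0) # (1 - exp(-10)) / 10
#' @export
beta_poisson_pmf <- function(alpha, beta, nu, n) {
  stopifnot(alpha > 0, beta > 0, nu >= 0)
  n <- as.integer(n)
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  if (nu == 0) return(as.numeric(n == 0L))
  vapply(n, function(k) bp_one(alpha, beta, nu, k), numeric(1))
}

bp_one <- function(alpha, beta, nu, k) {
  # substitute u = pbeta(lambda): the integrand dpois(k, nu * qbeta(u))
  # is bounded on (0, 1) with no endpoint singularities, so adaptive
  # quadrature is reliable even for sharply peaked cases
  h <- function(u) dpois(k, nu * stats::qbeta(u, alpha, beta))
  # restrict to the region where the Poisson factor is non-negligible
  lam_lo <- max(0, (k - 40 * sqrt(k + 1)) / nu)
  lam_hi <- min(1, (k + 40 * sqrt(k + 1)) / nu)
  if (lam_lo >= 1) lam_lo <- 1 - 1e-12
  u_lo <- stats::pbeta(lam_lo, alpha, beta)
  u_hi <- stats::pbeta(lam_hi, alpha, beta)
  if (u_hi - u_lo < 1e-300) return(0)
  opt <- stats::optimize(function(u) -h(u), interval = c(u_lo, u_hi))
  m <- min(max(opt$minimum, u_lo + 1e-12), u_hi - 1e-12)
  quad <- function(a, b) {
    tryCatch(
      stats::integrate(h, a, b, rel.tol = 1e-12, abs.tol = 1e-16,
                       subdivisions = 2000L)$value,
      error = function(e) {
        u <- seq(a, b, length.out = 4001L) # Simpson fallback
        w <- c(1, rep(c(4, 2), 1999L), 4, 1)
        sum(w * h(u)) * (b - a) / 4000 / 3
      })
  }
  v <- quad(u_lo, m) + quad(m, u_hi)
  min(max(v, 0), 1)
}

#' Mean and variance of a count distribution
#'
#' @param dist A `burst_dist` (or bare probability vector over counts 0..N).
#' @return A one-row tibble with columns `mean` and `variance`. For the
#'   two-state model the mean equals `nu * alpha / (alpha + beta)`.
#' @export
distribution_moments <- function(dist) {
  p <- as.numeric(dist)
  m <- seq_along(p) - 1
  mu <- sum(m * p)
  tibble::tibble(mean = mu, variance = sum(m^2 * p) - mu^2)
}

#' Binomial thinning of a count distribution
#'
#' Models random technical loss: each molecule is observed independently with
#' probability `p`, so the observed distribution is the binomial mixture
#' `P'(m) = sum_n Bin(m | n, p) P(n)`. For any generalized telegraph model
#' this equals the steady state with the ejection rate rescaled to
#' `p * k_eject` (the capture-yield rescaling theorem), which is why
#' inference never needs to thin explicitly.
#'
#' @param dist A `burst_dist`.
#' @param p Capture probability in (0, 1].
#' @return A `burst_dist` on the same support.
#' @export
thin_distribution <- function(dist, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("`p` must be in (0, 1]", call. = FALSE)
  q <- as.numeric(dist)
  if (p == 1) return(new_burst_dist(q))
  N <- length(q) - 1L
  out <- vapply(0:N, function(m) {
    ns <- m:N
    sum(dbinom(m, ns, p) * q[ns + 1L])
  }, numeric(1))
  new_burst_dist(out)
}

#' Per-cell distribution over multiple alleles
#'
#' Assuming uncorrelated alleles, the cell-level count is the sum of
#' independent per-allele counts, so the per-cell distribution is the n-fold
#' discrete self-convolution of the single-allele distribution. The support
#' extends to `n_alleles * N`.
#'
#' @param dist A single-allele `burst_dist`.
#' @param n_alleles Positive integer.
#' @return A `burst_dist` over `0..(n_alleles * N)`.
#' @export
convolve_alleles <- function(dist, n_alleles) {
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L)
    stop("`n_alleles` must be a positive integer", call. = FALSE)
  p <- as.numeric(dist)
  if (n_alleles == 1L) return(new_burst_dist(p))
  out <- p
  for (a in seq_len(n_alleles - 1L)) {
    out <- stats::convolve(out, rev(p), type = "open")
    out[out < 0] <- 0 # FFT roundoff
  }
  new_burst_dist(out)
}
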