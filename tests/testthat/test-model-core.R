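test_that("generator conserves probability and has valid structure", {
  spec <- two_state()
  r <- rates_2s()
  G <- build_generator(spec, r, truncation = 30)
  expect_equal(dim(G), c(62, 62))
  expect_lt(max(abs(Matrix::rowSums(G))), 1e-12)
  offdiag <- G - Matrix::Diagonal(x = Matrix::diag(G))
  expect_gte(min(offdiag), 0)

  # 1-state, N = 3: 4x4 birth-death generator of Poisson(1)
  G1 <- as.matrix(build_generator(telegraph_model(1L, n_alleles = 1L),
                                  rates_1s(1, 1), truncation = 3))
  expect_equal(dim(G1), c(4, 4))
  expect_equal(G1[1, 2], 1) # birth at rate nu
  expect_equal(G1[3, 2], 2) # death at rate m * k_decay
  expect_lt(max(abs(rowSums(G1))), 1e-12)

  # zero ejection: the only transitions out of the m=0 block switch gene state
  G0 <- as.matrix(build_generator(spec, telegraph_rates(
    k_on = 0.01, k_off = 0.1, k_eject = 0, k_decay = 0.005), truncation = 5))
  expect_equal(sum(G0[1:2, -(1:2)] != 0), 0)
})

test_that("mismatched rate count for the model size is an error", {
  expect_error(build_generator(telegraph_model(3L), rates_2s(), 10),
               "switching rate")
  expect_error(steady_state(telegraph_model(1L), rates_2s()),
               "switching rate")
})

test_that("steady state reduces to Poisson for the one-state model", {
  d <- steady_state(telegraph_model(1L, n_alleles = 1L), rates_1s(2, 1))
  expect_equal(as.numeric(d)[1], exp(-2), tolerance = 1e-10)
  expect_equal(as.numeric(d)[1:10], dpois(0:9, 2), tolerance = 1e-10)
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("two-state steady state matches the Beta-Poisson oracle", {
  spec <- two_state()
  r <- rates_2s(0.01, 0.1, 0.5, 0.005)
  d <- steady_state(spec, r)
  sp <- burstkit:::scaled_params(r)
  bp <- beta_poisson_pmf(sp$alpha, sp$beta, sp$nu, 0:attr(d, "truncation"))
  expect_lt(max(abs(as.numeric(d) - bp)), 1e-6)
})

test_that("zero ejection gives a point mass at zero", {
  d <- steady_state(two_state(), telegraph_rates(
    k_on = 0.01, k_off = 0.1, k_eject = 0, k_decay = 0.005))
  expect_equal(as.numeric(d)[1], 1)
})

test_that("block-elimination and QR null-space routes agree", {
  for (mk in list(
    function() list(two_state(), rates_2s()),
    function() list(telegraph_model(3L, n_alleles = 1L), rates_3s()),
    function() list(telegraph_model(1L, n_alleles = 1L), rates_1s(5, 1)))) {
    sr <- mk()
    d <- steady_state(sr[[1]], sr[[2]])
    dq <- steady_state(sr[[1]], sr[[2]],
                       truncation = attr(d, "truncation"),
                       method = "nullspace")
    expect_lt(max(abs(as.numeric(d) - as.numeric(dq))), 1e-10)
  }
})

test_that("steady state is invariant to truncation beyond the adaptive one", {
  r <- rates_2s()
  d <- steady_state(two_state(), r)
  N <- attr(d, "truncation")
  d2 <- steady_state(two_state(), r, truncation = N + 200L)
  expect_lt(max(abs(as.numeric(d) - as.numeric(d2)[seq_len(N + 1)])), 1e-10)
})

test_that("beta_poisson_pmf handles the analytic special cases", {
  expect_equal(beta_poisson_pmf(2, 3, 0, c(0, 1, 5)), c(1, 0, 0))
  # alpha = beta = 1: uniform mixing, P(0) = (1 - e^-nu)/nu
  expect_equal(beta_poisson_pmf(1, 1, 10, 0), (1 - exp(-10)) / 10,
               tolerance = 1e-10)
  # frozen value from two independent raw-integrand quadratures
  expect_equal(beta_poisson_pmf(2, 5, 8, 3), 0.148548153176,
               tolerance = 1e-10)
  # sums to one
  expect_equal(sum(beta_poisson_pmf(0.5, 2, 20, 0:200)), 1, tolerance = 1e-8)
  expect_error(beta_poisson_pmf(2, 3, 1, -1), "non-negative")
})

test_that("distribution moments match analytic telegraph values", {
  m <- distribution_moments(new_poisson_dist(2, 40))
  expect_equal(m$mean, 2, tolerance = 1e-8)
  expect_equal(m$variance, 2, tolerance = 1e-8)

  # alpha = beta = 1, nu = 10: mean = nu * alpha / (alpha + beta) = 5
  kd <- 0.01
  d <- steady_state(two_state(), rates_2s(kd, kd, 10 * kd, kd))
  expect_equal(distribution_moments(d)$mean, 5, tolerance = 1e-6)

  # 20-set grid: moments equal the direct summation oracle
  withr::with_seed(7, {
    for (i in 1:20) {
      r <- rates_2s(k_on = rlnorm(1, log(0.01), 1),
                    k_off = rlnorm(1, log(0.1), 1),
                    k_eject = rlnorm(1, log(0.3), 0.7))
      d <- steady_state(two_state(), r)
      p <- as.numeric(d)
      mm <- seq_along(p) - 1
      mo <- distribution_moments(d)
      expect_equal(mo$mean, sum(mm * p), tolerance = 1e-12)
      expect_equal(mo$variance, sum(mm^2 * p) - sum(mm * p)^2,
                   tolerance = 1e-12)
    }
  })
})

test_that("binomial thinning behaves like the capture-loss model", {
  d <- new_poisson_dist(2, 40)
  expect_equal(as.numeric(thin_distribution(d, 1)), as.numeric(d))
  pm <- new_burst_dist(c(1, rep(0, 10)))
  expect_equal(as.numeric(thin_distribution(pm, 0.3))[1], 1)
  # Poisson thinning: thin(Poisson(2), 0.5) = Poisson(1)
  th <- thin_distribution(d, 0.5)
  expect_equal(as.numeric(th)[1], exp(-1), tolerance = 1e-10)
  expect_equal(as.numeric(th)[1:10], dpois(0:9, 1), tolerance = 1e-10)
  expect_error(thin_distribution(d, 0), "in \\(0, 1\\]")
  expect_error(thin_distribution(d, 1.2), "in \\(0, 1\\]")
})

test_that("thinning a telegraph steady state equals rescaling the eject rate", {
  # the capture-yield theorem, for all three model sizes
  cases <- list(
    list(telegraph_model(1L, n_alleles = 1L), rates_1s(3, 1)),
    list(two_state(), rates_2s(0.01, 0.05, 0.4, 0.005)),
    list(telegraph_model(3L, n_alleles = 1L), rates_3s()))
  for (cs in cases) {
    d <- steady_state(cs[[1]], cs[[2]], tol = 1e-12)
    for (p in c(0.05, 0.5)) {
      th <- thin_distribution(d, p)
      r2 <- cs[[2]]
      r2$k_eject <- p * r2$k_eject
      ds <- steady_state(cs[[1]], r2, truncation = attr(th, "truncation"))
      expect_lt(max(abs(as.numeric(th) - as.numeric(ds))), 1e-8)
    }
  }
})

test_that("allele convolution sums independent allele distributions", {
  d1 <- new_poisson_dist(1, 30)
  expect_equal(as.numeric(convolve_alleles(d1, 1)), as.numeric(d1))
  pm1 <- new_burst_dist(c(0, 1, rep(0, 5)))
  expect_equal(which.max(as.numeric(convolve_alleles(pm1, 2))), 3L) # count 2
  # Poisson additivity: two alleles at rate 1 behave like one at rate 2
  c2 <- convolve_alleles(d1, 2)
  expect_equal(as.numeric(c2)[1], exp(-2), tolerance = 1e-8)
  expect_equal(as.numeric(c2)[1:15], dpois(0:14, 2), tolerance = 1e-8)
  m <- distribution_moments(c2)
  expect_equal(m$mean, 2, tolerance = 1e-6)
})
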