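test_that("log likelihood equals the cross-entropy form", {
  unif <- new_burst_dist(rep(0.1, 10))
  counts <- rep(0:9, 10)
  expect_equal(log_likelihood(unif, counts), 100 * log(0.1),
               tolerance = 1e-10)

  d <- new_poisson_dist(2, 30)
  expect_equal(log_likelihood(d, c(0, 1, 2)), -6 + log(4), tolerance = 1e-8)

  # brute-force per-cell loop on a random case
  withr::with_seed(2, {
    p <- runif(20); p <- p / sum(p)
    dd <- new_burst_dist(p)
    cnt <- sample(0:19, 500, replace = TRUE)
    brute <- sum(vapply(cnt, function(m) log(as.numeric(dd)[m + 1]),
                        numeric(1)))
    expect_equal(log_likelihood(dd, cnt), brute, tolerance = 1e-10)
  })

  # probability floor for counts beyond the support
  expect_warning(ll <- log_likelihood(new_poisson_dist(1, 5), c(0, 50)),
                 "floor")
  expect_lt(ll, log(1e-299))
  expect_error(log_likelihood(d, integer(0)), "empty")
})

test_that("log-normal prior moments invert to the stated log-space values", {
  pr <- prior_spec()
  ls <- burstkit:::prior_logspace(pr, telegraph_model(2L))
  expect_equal(ls$sigma[1]^2, log(1 + 10^2), tolerance = 1e-12) # ln(101)
  expect_equal(ls$mu[1], log(0.01) - log(101) / 2, tolerance = 1e-12)
  expect_equal(ls$names, c("k_on", "k_off", "k_eject"))

  # density at the median: dlnorm(exp(mu)) = 1/(x sigma sqrt(2 pi))
  spec1 <- telegraph_model(1L)
  ls1 <- burstkit:::prior_logspace(pr, spec1)
  x <- exp(ls1$mu)
  lp <- log_prior(pr, rates_1s(x, 0.005), spec1)
  expect_equal(lp, log(1 / (x * ls1$sigma * sqrt(2 * pi))),
               tolerance = 1e-10)

  # symmetry in log space: the Gaussian part is even around mu
  lp_hi <- log_prior(pr, rates_1s(exp(ls1$mu + 1), 0.005), spec1)
  lp_lo <- log_prior(pr, rates_1s(exp(ls1$mu - 1), 0.005), spec1)
  expect_equal(lp_hi + (ls1$mu + 1), lp_lo + (ls1$mu - 1), tolerance = 1e-10)
})

test_that("r-hat behaves as the potential scale reduction factor", {
  withr::with_seed(31, {
    mat <- cbind(rnorm(1000), rnorm(1000))
    expect_gt(rhat(mat), 0.99)
    expect_lt(rhat(mat), 1.02)
  })
  # two deterministic chains N(0,1)-like and shifted by 10, unsplit formula
  z <- qnorm((1:1000 - 0.5) / 1000)
  z <- z / sd(z)
  mat2 <- cbind(z, z + 10)
  n <- 1000; W <- 1; B <- n * var(c(0, 10))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(rhat(mat2, split = FALSE), expected, tolerance = 1e-6)
  expect_equal(expected, 7.14, tolerance = 0.01)
  # identical duplicated chains: B = 0
  expect_equal(rhat(cbind(z, z), split = FALSE), sqrt(999 / 1000),
               tolerance = 1e-6)
  expect_warning(r0 <- rhat(cbind(rep(1, 10), rep(1, 10))), "zero within")
  expect_equal(r0, 1)
  expect_error(rhat(matrix(1:8, ncol = 1)), "2 chains")
})

test_that("posterior summaries propagate joint-draw correlations", {
  # draws with k_eject = 2 * k_off exactly: burst size is a point mass at 2
  withr::with_seed(4, {
    k_off <- rlnorm(400, log(0.1), 0.5)
    draws <- cbind(k_on = rep(log(0.01), 400), k_off = log(k_off),
                   k_eject = log(2 * k_off))
  })
  ch <- forge_chains(list(draws[1:200, ], draws[201:400, ]), counts = 0:5)
  s <- suppressWarnings(summarize_posterior(ch)) # k_on is constant by design
  bs <- s[s$parameter == "burst_size", ]
  expect_equal(bs$median, 2, tolerance = 1e-12)
  expect_equal(bs$mad, 0, tolerance = 1e-12)

  # unscaled MAD definition: pooled draws 1..5 -> median 3, MAD 1
  expect_equal(burstkit:::mad_raw(1:5), 1)
  expect_equal(median(1:5), 3L)

  # shuffling k_eject against k_off inflates the burst-size MAD
  joint_mad <- bs$mad
  shuf <- draws
  shuf[, "k_eject"] <- sample(shuf[, "k_eject"])
  ch2 <- forge_chains(list(shuf[1:200, ], shuf[201:400, ]), counts = 0:5)
  s2 <- suppressWarnings(summarize_posterior(ch2))
  expect_gt(s2$mad[s2$parameter == "burst_size"], joint_mad + 0.1)
})

test_that("MCMC chains are seed-deterministic and recover known rates", {
  kd <- 0.005
  r <- rates_2s(0.02, 0.08, 0.5, kd)
  d <- convolve_alleles(steady_state(two_state(), r), 2L)
  withr::with_seed(6, {
    cnt <- sample(seq_along(d) - 1L, 2000, replace = TRUE,
                  prob = as.numeric(d))
  })
  ch1 <- run_mcmc(cnt, telegraph_model(2L), prior_spec(), k_decay = kd,
                  n_chains = 2L, n_samples = 20000, seed = 99)
  ch2 <- run_mcmc(cnt, telegraph_model(2L), prior_spec(), k_decay = kd,
                  n_chains = 2L, n_samples = 20000, seed = 99)
  expect_identical(ch1$draws, ch2$draws)

  s <- summarize_posterior(ch1, counts = cnt)
  k_on_row <- s[s$parameter == "k_on", ]
  expect_gt(0.02, k_on_row$ci_lower)
  expect_lt(0.02, k_on_row$ci_upper)
  expect_lt(attr(s, "rhat_max"), 1.1)
  expect_equal(attr(s, "expression"), mean(cnt))

  expect_error(run_mcmc(rep(0L, 10), telegraph_model(2L), prior_spec(),
                        k_decay = kd), "insufficient data")
  expect_error(run_mcmc(cnt, telegraph_model(2L), prior_spec(),
                        k_decay = -1), "positive")
})

test_that("maximum likelihood estimation matches analytic cases", {
  withr::with_seed(8, cnt <- rpois(500, 3))
  kd <- 0.01
  fit <- mle_fit(cnt, telegraph_model(1L, n_alleles = 1L), k_decay = kd,
                 seed = 1)
  # Poisson MLE: nu / k_decay equals the sample mean
  expect_equal(fit$rates$k_eject / kd, mean(cnt), tolerance = 1e-3)

  # likelihood at the MLE is at least that at the posterior median
  r <- rates_2s(0.02, 0.08, 0.5, 0.005)
  d <- convolve_alleles(steady_state(two_state(), r), 2L)
  withr::with_seed(9, cnt2 <- sample(seq_along(d) - 1L, 1500, replace = TRUE,
                                     prob = as.numeric(d)))
  ch <- run_mcmc(cnt2, telegraph_model(2L), prior_spec(), k_decay = 0.005,
                 n_chains = 2L, n_samples = 10000, seed = 3)
  med <- apply(burstkit:::pooled_draws(ch), 2, median)
  ll_med <- burstkit:::loglik_at(ch, med)
  mle2 <- mle_fit(cnt2, telegraph_model(2L), k_decay = 0.005, seed = 4)
  expect_gte(mle2$logLik, ll_med - 1e-6)
})

test_that("fit_telegraph produces tidy and glance output", {
  r <- rates_2s(0.02, 0.08, 0.5, 0.005)
  d <- convolve_alleles(steady_state(two_state(), r), 2L)
  withr::with_seed(10, cnt <- sample(seq_along(d) - 1L, 1200, replace = TRUE,
                                     prob = as.numeric(d)))
  fit <- fit_telegraph(cnt, k_decay = 0.005, n_chains = 2L,
                       n_samples = 10000, seed = 12)
  td <- tidy(fit)
  expect_true(all(c("k_on", "k_off", "k_eject", "off_time", "burst_size")
                  %in% td$parameter))
  expect_true(all(td$ci_lower <= td$median & td$median <= td$ci_upper))
  gl <- glance(fit)
  expect_equal(gl$n_cells, 1200)
  expect_equal(gl$model_states, 2)
  expect_error(fit_telegraph(cnt), "decay rate required")
  expect_s3_class(autoplot(fit), "ggplot")

  # half-life interface: k_decay = log(2) / (60 * hours)
  fit2 <- fit_telegraph(cnt, half_life_hours = log(2) / (60 * 0.005),
                        n_chains = 2L, n_samples = 5000, seed = 12)
  expect_equal(fit2$k_decay, 0.005, tolerance = 1e-12)
})
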