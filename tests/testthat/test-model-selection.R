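test_that("AIC formula and penalty monotonicity", {
  expect_equal(aic(-100, 3), 206)
  expect_equal(aic(0, 1), 2)
  expect_gt(aic(-50, 5), aic(-50, 3)) # same fit, more parameters
  expect_error(aic(-10, 0), ">= 1")
})

test_that("WAIC matches its formula on controlled inputs", {
  # identical draws: p_waic = 0 and WAIC = -2 * sum(ll)
  ll <- matrix(rep(c(-1.2, -0.7, -2.0), each = 4), nrow = 4)
  expect_equal(waic(ll), -2 * sum(ll[1, ]), tolerance = 1e-12)

  # toy 2-draw x 2-cell matrix: hand-computed value
  ll2 <- matrix(c(-1, -2, -0.5, -1.5), nrow = 2)
  lppd <- log(mean(exp(ll2[, 1]))) + log(mean(exp(ll2[, 2])))
  p_waic <- var(ll2[, 1]) + var(ll2[, 2])
  expect_equal(waic(ll2), -2 * (lppd - p_waic), tolerance = 1e-12)

  # invariant to draw order
  expect_equal(waic(ll2), waic(ll2[2:1, ]), tolerance = 1e-12)
  expect_error(waic(matrix(-1, nrow = 1)), "2 posterior draws")
})

test_that("ties in the criteria resolve towards fewer states", {
  counts <- rep(0:3, c(5, 3, 2, 1))
  mk_fit <- function(n_states, max_ll) {
    spec <- telegraph_model(n_states, n_alleles = 1L)
    ls <- burstkit:::prior_logspace(prior_spec(), spec)
    draws <- rbind(ls$mu, ls$mu + 0.01)
    colnames(draws) <- ls$names
    ch <- forge_chains(list(draws), counts, spec = spec, k_decay = 0.005,
                       logliks = list(c(max_ll, max_ll - 1)))
    structure(list(chains = ch, summary = NULL, mle = NULL, spec = spec,
                   k_decay = 0.005, counts = as.integer(counts),
                   reruns = 0L, seed = 1L), class = "burst_fit")
  }
  # engineered so 2k - 2 lnL is equal for both models
  cmp <- select_model(list(mk_fit(1L, -100), mk_fit(2L, -98)))
  expect_equal(cmp$aic[1], cmp$aic[2])
  expect_equal(attr(cmp, "winner_aic"), 1L)

  # mismatched counts are rejected
  bad <- mk_fit(1L, -100)
  bad$counts <- c(bad$counts, 1L)
  expect_error(select_model(list(bad, mk_fit(2L, -98))), "identical counts")
})

test_that("nested model likelihood is non-decreasing in model size", {
  withr::with_seed(15, cnt <- rpois(800, 4))
  kd <- 0.01
  m1 <- mle_fit(cnt, telegraph_model(1L, n_alleles = 1L), k_decay = kd,
                seed = 1)
  m2 <- mle_fit(cnt, telegraph_model(2L, n_alleles = 1L), k_decay = kd,
                seed = 2, starts = 8L)
  expect_gte(m2$logLik, m1$logLik - 0.02)
})

test_that("compare_states declares a sensible winner on Poisson data", {
  withr::with_seed(16, cnt <- rpois(1500, 5))
  cmp <- compare_states(cnt, k_decay = 0.01, states = 1:2,
                        n_chains = 2L, n_samples = 4000, seed = 21,
                        n_alleles = 1L)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$k, c(1L, 3L))
  expect_equal(attr(cmp, "winner_aic"), 1L)
})
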