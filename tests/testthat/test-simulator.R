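test_that("SSA draws match the CME steady state", {
  # 1-state nu = 2: sampling-error bound on the mean of 50k draws
  x <- gillespie_cell(telegraph_model(1L, n_alleles = 1L), rates_1s(2, 1),
                      n_cells = 50000, seed = 101)
  expect_lt(abs(mean(x) - 2), 3 * sqrt(2 / 50000))

  # 2-state alpha = beta = 1, nu = 10: TV < 0.02 against the CME solution
  kd <- 0.01
  r <- rates_2s(kd, kd, 10 * kd, kd)
  y <- gillespie_cell(two_state(), r, n_cells = 50000, seed = 102)
  expect_lt(tv_distance(y, steady_state(two_state(), r)), 0.02)
})

test_that("a gene that can never activate produces zero counts", {
  r <- telegraph_rates(k_on = 1e-12, k_off = 0.1, k_eject = 0.5,
                       k_decay = 0.005)
  x <- gillespie_cell(two_state(), r, n_cells = 200, burn_in = 1000,
                      seed = 5)
  expect_true(all(x == 0))
})

test_that("simulate_dataset is reproducible and respects yield", {
  truth <- make_truth(5)
  a <- simulate_dataset(truth, n_cells = 300, seed = 42)
  b <- simulate_dataset(truth, n_cells = 300, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(dim(a$counts), c(5L, 300L))
  expect_true(all(a$counts >= 0))

  # thinning linearity: mean scales by the yield
  big <- simulate_dataset(truth, n_cells = 4000, yield = 1, seed = 7)
  thin <- simulate_dataset(truth, n_cells = 4000, yield = 0.05, seed = 7)
  ratio <- rowMeans(thin$counts) / rowMeans(big$counts)
  expect_true(all(abs(ratio - 0.05) < 0.02))
})

test_that("cohort histograms match per-gene steady states at yield 1", {
  truth <- make_truth(2, seed = 3)
  cohort <- simulate_dataset(truth, n_cells = 50000, yield = 1,
                             n_alleles = 1L, seed = 9)
  for (i in 1:2) {
    r <- telegraph_rates(k_on = truth$k_on[i], k_off = truth$k_off[i],
                         k_eject = truth$k_eject[i],
                         k_decay = truth$k_decay[i])
    d <- steady_state(two_state(), r)
    expect_lt(tv_distance(cohort$counts[i, ], d), 0.02)
  }
})

test_that("copula coupling hits the target Spearman and keeps marginals", {
  truth <- make_truth(4, seed = 11)
  base <- simulate_dataset(truth, n_cells = 20000, seed = 12)
  pairs <- tibble::tibble(gene_a = c("g001", "g003"),
                          gene_b = c("g002", "g004"))

  # rho = 0: empirical Spearman within the null sampling band
  c0 <- simulate_correlated_pairs(base, pairs[1, ], rho = 0, seed = 13)
  expect_lt(abs(c0$pairs$rho_achieved), 0.03)

  # rho = 0.5 on moderately expressed genes
  c5 <- simulate_correlated_pairs(base, pairs, rho = 0.5, seed = 14)
  expect_true(all(abs(c5$pairs$rho_achieved - 0.5) < 0.07))

  # marginals preserved: per-gene TV below 0.05 against the model pmf
  for (g in c("g001", "g002")) {
    i <- match(g, truth$gene)
    r <- telegraph_rates(k_on = truth$k_on[i], k_off = truth$k_off[i],
                         k_eject = truth$k_eject[i],
                         k_decay = truth$k_decay[i])
    d <- convolve_alleles(steady_state(two_state(), r), 2L)
    expect_lt(tv_distance(c5$counts[g, ], d), 0.05)
  }
  expect_error(simulate_correlated_pairs(base, pairs, rho = 1.5),
               "-1, 1")
})

test_that("decay course simulation has exact spike-in structure", {
  hl <- c(gA = 6.93, gB = 2)
  sim <- simulate_decay_course(hl, timepoints = c(0, 1, 2, 4, 6.93, 12, 24),
                               noise_cv = 0, seed = 21)
  course <- spikein_normalize(sim$counts, sim$spikein_amounts,
                              timepoints = sim$timepoints)
  conc <- course$concentrations
  # noiseless: value at t = half-life is exactly half of t = 0
  expect_equal(conc["gA", "t6.93"] / conc["gA", "t0"], 2^(-6.93 / 6.93),
               tolerance = 1e-9)
  # per-sample scale factors recoverable from spike-ins within 1%
  rec <- 1 / course$scale_factors
  rec <- rec / rec[1]
  expect_true(all(abs(rec / sim$scale_factors - 1) < 0.01))
  # determinism
  sim2 <- simulate_decay_course(hl, timepoints = c(0, 1, 2, 4, 6.93, 12, 24),
                                noise_cv = 0, seed = 21)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_decay_course(hl, timepoints = c(1, 2, 4)),
               "from 0")
})
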