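test_that("depth normalization rescales to reads-per-cell and rounds", {
  m <- matrix(c(10, 90, 40, 160), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  out <- depth_normalize(m, depth_scale = 30000)
  expect_equal(out["g1", "c1"], 3000L) # 10/100 * 30000
  expect_equal(out["g2", "c2"], 24000L)

  # fixed point: counts already summing to the target are unchanged
  m2 <- matrix(c(100L, 200L, 150L, 150L), nrow = 2,
               dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_equal(depth_normalize(m2, 300), m2)

  # equals the brute-force per-cell loop
  withr::with_seed(61, m3 <- matrix(rpois(200, 5), nrow = 10,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("c", 1:20))))
  m3[1, ] <- m3[1, ] + 1L # guard against all-zero cells
  out3 <- depth_normalize(m3, 1000)
  for (j in c(1, 7, 20)) {
    expect_equal(out3[, j],
                 round(m3[, j] / sum(m3[, j]) * 1000))
  }
  # rank order within a cell is preserved (rounding ties aside)
  expect_true(all(diff(out3[order(m3[, 3]), 3]) >= 0))

  zero <- m3; zero[, 5] <- 0L
  expect_error(depth_normalize(zero), "zero total")
  expect_error(depth_normalize(m3, -1), "positive")
})

test_that("pair eligibility enforces the detection fraction in both samples", {
  a <- rbind(g1 = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1),
             g2 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # 10% in a
             g3 = rep(1, 10))
  b <- a
  b["g2", ] <- 0; b["g2", 1] <- 1 # 10% in b too
  pairs <- eligible_pairs(a, b, detection_fraction = 0.10)
  expect_true(nrow(pairs) == 3) # all three genes at >= 10% in both
  # drop g2 below threshold in one sample only
  b2 <- b; b2["g2", ] <- 0
  pairs2 <- eligible_pairs(a, b2, detection_fraction = 0.10)
  expect_identical(sort(unique(c(pairs2$gene_a, pairs2$gene_b))),
                   c("g1", "g3"))
  expect_error(eligible_pairs(a, b, detection_fraction = 0), "in \\(0, 1\\)")
})

test_that("Spearman correlations equal rank-then-Pearson with midranks", {
  withr::with_seed(62, {
    m <- matrix(rpois(5 * 60, 3), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:60)))
  })
  pairs <- tibble::tibble(gene_a = c("g1", "g2"), gene_b = c("g3", "g5"))
  rho <- burstkit:::pair_spearman(m, pairs)
  brute <- vapply(seq_len(2), function(k)
    cor(rank(m[pairs$gene_a[k], ]), rank(m[pairs$gene_b[k], ])),
    numeric(1))
  expect_equal(rho, brute, tolerance = 1e-12)
  base_r <- vapply(seq_len(2), function(k)
    cor(m[pairs$gene_a[k], ], m[pairs$gene_b[k], ], method = "spearman"),
    numeric(1))
  expect_equal(rho, base_r, tolerance = 1e-12)
})

test_that("identical matrices give a zero correlation shift", {
  withr::with_seed(63, {
    m <- matrix(rpois(10 * 200, 4) + rbinom(10 * 200, 1, 0.5), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:200)))
  })
  cs <- correlation_shift(m, m, m, m, depth_scale = 100)
  expect_true(all(cs$perturbation$delta_rho == 0))
  expect_equal(cs$summary$mad_delta, c(0, 0))
  expect_equal(cs$summary$mad_abs_delta, c(0, 0))
})

test_that("perfectly monotone pairs have Spearman correlation one", {
  m <- rbind(g1 = 1:50, g2 = (1:50)^2, g3 = rep(c(1L, 2L), 25))
  colnames(m) <- paste0("c", 1:50)
  pairs <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  expect_equal(burstkit:::pair_spearman(m, pairs), 1, tolerance = 1e-12)
})

test_that("replicate-vs-replicate shifts are centred at zero", {
  truth <- make_truth(12, seed = 64)
  r1 <- simulate_dataset(truth, n_cells = 5000, seed = 65)
  r2 <- simulate_dataset(truth, n_cells = 5000, seed = 66)
  cs <- correlation_shift(r1$counts, r1$counts, r1$counts, r2$counts,
                          depth_scale = 1000)
  expect_lt(abs(cs$summary$median_delta[2]), 0.02)
})
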