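test_that("cell filter clips covariate tails and mitochondrial outliers", {
  withr::with_seed(41, {
    n <- 1000
    counts <- matrix(rpois(50 * n, lambda = rep(rlnorm(50, 2, 1), n)),
                     nrow = 50, dimnames = list(sprintf("gene%02d", 1:50),
                                                sprintf("c%04d", 1:n)))
    mito <- rep(0.01, n)
  })
  qc <- filter_cells(counts, q = 0.90, mito_max = 0.05,
                     mito_fraction = mito)
  # brute-force expected retention from the empirical quantile bands
  tot <- colSums(counts); feat <- colSums(counts > 0)
  bt <- quantile(tot, c(0.05, 0.95), names = FALSE)
  bf <- quantile(feat, c(0.05, 0.95), names = FALSE)
  keep <- tot >= bt[1] & tot <= bt[2] & feat >= bf[1] & feat <= bf[2]
  expect_identical(unname(qc$kept), unname(keep))
  # ~90% of cells on continuous-ish covariates
  frac <- sum(qc$kept) / n
  expect_gte(frac, 0.85)
  expect_lte(frac, 0.901)

  # degenerate: identical covariates retain everything
  const <- matrix(5L, nrow = 3, ncol = 20,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:20)))
  expect_true(all(filter_cells(const, mito_fraction = rep(0, 20))$kept))

  # one high-mito cell is removed
  mito2 <- rep(0, 20); mito2[7] <- 0.5
  qc2 <- filter_cells(const, mito_max = 0.05, mito_fraction = mito2)
  expect_false(qc2$kept[7])
  expect_equal(sum(qc2$kept), 19)
})

test_that("mitochondrial genes are recognized by name prefix", {
  m <- rbind(`MT-CO1` = c(50L, 1L), GAPDH = c(50L, 99L))
  colnames(m) <- c("bad", "good")
  qc <- filter_cells(m, q = 0.99, mito_max = 0.05)
  expect_identical(unname(qc$kept), c(FALSE, TRUE))
  expect_error(filter_cells(m, q = 1.2), "in \\(0, 1\\)")
})

test_that("gene filter applies the five criteria with strict inequalities", {
  base <- tibble::tibble(
    gene = "g", expression = 0.5,
    k_on_median = 0.01, k_on_mad = 0.003,
    k_off_median = 0.1, k_off_mad = 0.03,
    k_eject_median = 0.05, k_eject_mad = 0.015,
    burst_size = 0.5, burst_size_mad = 0.15
  )
  expect_true(filter_genes(base)$pass)

  high_ratio <- base; high_ratio$k_on_mad <- 0.008 # ratio 0.8
  expect_false(filter_genes(high_ratio)$pass)

  boundary <- base; boundary$k_on_mad <- 0.0075 # ratio exactly 0.75
  expect_false(filter_genes(boundary)$pass)

  low_expr <- base; low_expr$expression <- 0.005
  expect_false(filter_genes(low_expr)$pass)
  at_thresh <- base; at_thresh$expression <- 0.01 # exactly 0.01 fails (>)
  expect_false(filter_genes(at_thresh)$pass)

  expect_error(filter_genes(base[, -2]), "missing column")
})

test_that("gene filter is a pure, order-independent predicate", {
  withr::with_seed(43, {
    tbl <- tibble::tibble(
      gene = sprintf("g%03d", 1:100),
      expression = rlnorm(100, log(0.05), 2),
      k_on_median = rlnorm(100, log(0.01), 1),
      k_on_mad = rlnorm(100, log(0.005), 1),
      k_off_median = rlnorm(100, log(0.1), 1),
      k_off_mad = rlnorm(100, log(0.05), 1),
      k_eject_median = rlnorm(100, log(0.05), 1),
      k_eject_mad = rlnorm(100, log(0.02), 1),
      burst_size = rlnorm(100, log(1), 1),
      burst_size_mad = rlnorm(100, log(0.5), 1)
    )
  })
  res <- filter_genes(tbl)
  # brute-force row scan
  brute <- vapply(seq_len(100), function(i) {
    r <- tbl[i, ]
    (r$k_on_mad / r$k_on_median < 0.75) &&
      (r$k_off_mad / r$k_off_median < 0.75) &&
      (r$k_eject_mad / r$k_eject_median < 0.75) &&
      (r$burst_size_mad / r$burst_size < 0.75) &&
      (r$expression > 0.01)
  }, logical(1))
  expect_identical(res$pass, brute)
  # idempotent and order-independent
  res2 <- filter_genes(res)
  expect_identical(res2$pass, res$pass)
  perm <- sample(100)
  expect_identical(filter_genes(tbl[perm, ])$pass, res$pass[perm])
})
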