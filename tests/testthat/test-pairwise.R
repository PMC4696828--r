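test_that("correlation scorers match hand examples and order negatives first", {
  expect_equal(score_pearson(pair_dataset(c(1, 2, 3), c(6, 4, 2)))[1, 1], -1)
  expect_equal(score_pearson(pair_dataset(c(1, 2, 3), c(1, 2, 3)))[1, 1], 1)
  ds <- pair_dataset(c(1, 2, 3), c(9, 4, 1))
  expect_equal(score_spearman(ds)[1, 1], -1)
  expect_equal(score_kendall(ds)[1, 1], -1)
  expect_equal(score_kendall(pair_dataset(c(1, 2, 3), c(2, 1, 3)))[1, 1],
               1 / 3, tolerance = 1e-12)
  expect_equal(score_ordering(score_pearson(ds)), "ASC_SIGNED")
})

test_that("pearson, spearman, kendall, dcov and hoeffding match brute-force oracles", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    y <- if (rep %% 3 == 0) round(rnorm(n)) else rnorm(n)  # inject ties
    ds <- pair_dataset(x, y)
    expect_equal(score_pearson(ds)[1, 1], oracle_pearson(x, y),
                 tolerance = 1e-10)
    expect_equal(score_spearman(ds)[1, 1], oracle_spearman(x, y),
                 tolerance = 1e-10)
    expect_equal(score_kendall(ds)[1, 1], oracle_kendall(x, y),
                 tolerance = 1e-10)
    expect_equal(score_dcov(ds)[1, 1], oracle_dcor(x, y),
                 tolerance = 1e-10)
    if (length(unique(x)) == n && length(unique(y)) == n) {
      expect_equal(score_hoeffding(ds)[1, 1], oracle_hoeffding(x, y),
                   tolerance = 1e-10)
    }
  }
  # hoeffding with ties against the tie-aware oracle
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    expect_equal(score_hoeffding(pair_dataset(x, y))[1, 1],
                 oracle_hoeffding(x, y), tolerance = 1e-10)
  }
})

test_that("spearman equals pearson on rank-transformed data", {
  set.seed(2)
  ds <- make_dataset(n = 25, n_mir = 3, n_rna = 4, seed = 2)
  ranked <- ds
  ranked$exprs <- apply(ds$exprs, 2, rank)
  expect_equal(unclass(score_spearman(ds)),
               unclass(score_pearson(ranked)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dependence measures behave under dependence and independence", {
  set.seed(9)
  x <- rnorm(50)
  expect_equal(score_dcov(pair_dataset(x, 2 * x + 1))[1, 1], 1,
               tolerance = 1e-10)
  # large-sample independence: small dcor, tiny hoeffding
  x2 <- rnorm(2000); y2 <- rnorm(2000)
  ds2 <- pair_dataset(x2, y2)
  expect_lt(score_dcov(ds2)[1, 1], 0.1)
  expect_lt(abs(score_hoeffding(ds2)[1, 1]), 0.01)
  # hoeffding needs n >= 5
  expect_error(score_hoeffding(pair_dataset(1:4, 4:1)), "5 samples")
})

test_that("RDC detects dependence, stays low under independence, and is deterministic", {
  set.seed(31)
  x <- rnorm(200)
  expect_gt(score_rdc(pair_dataset(x, x), seed = 7)[1, 1], 0.95)
  # a strong nonlinear relationship is still seen through the copula
  expect_gt(score_rdc(pair_dataset(x, x^2), seed = 7)[1, 1], 0.5)
  x2 <- rnorm(500); y2 <- rnorm(500)
  expect_lt(score_rdc(pair_dataset(x2, y2), seed = 7)[1, 1], 0.3)
  a <- score_rdc(make_dataset(50, 2, 3, seed = 4), seed = 11)
  b <- score_rdc(make_dataset(50, 2, 3, seed = 4), seed = 11)
  expect_identical(unclass(a), unclass(b))
})

test_that("mutual information hits the diagonal closed form and is non-negative", {
  for (B in c(2, 4, 5)) {
    x <- sample(seq_len(20 * B))
    expect_equal(score_mi(pair_dataset(x, x), bins = B)[1, 1], log2(B),
                 tolerance = 1e-12)
  }
  set.seed(13)
  ds <- make_dataset(n = 40, n_mir = 3, n_rna = 5, seed = 13)
  expect_true(all(unclass(score_mi(ds)) >= -1e-12))
  # independence: MI near zero in large samples
  x <- runif(5000); y <- runif(5000)
  expect_lt(score_mi(pair_dataset(x, y), bins = 8)[1, 1], 0.05)
  expect_error(score_mi(ds, bins = 1), ">= 2")
})

test_that("pseudo-knockout z-score follows the minimum-expression sample", {
  ds <- pair_dataset(c(5, 1, 3), c(2, 8, 5))
  expect_equal(score_zscore(ds)[1, 1], 1)          # |8 - 5| / 3
  # tied minima: first sample wins
  ds2 <- pair_dataset(c(1, 5, 1), c(4, 6, 2))
  mu <- mean(c(4, 6, 2)); s <- sd(c(4, 6, 2))
  expect_equal(score_zscore(ds2)[1, 1], abs(4 - mu) / s)
  # constant mRNA scores 0 with a warning
  expect_warning(z <- score_zscore(pair_dataset(c(5, 1, 3), c(2, 2, 2))),
                 "zero-variance")
  expect_equal(z[1, 1], 0)
  # signed variant keeps direction
  expect_equal(score_zscore(ds, signed = TRUE)[1, 1], 1)
})

test_that("scorers are invariant to sample permutation", {
  ds <- make_dataset(n = 21, n_mir = 2, n_rna = 3, seed = 17)
  set.seed(99)
  perm <- sample(nrow(ds$exprs))
  ds_p <- ds
  ds_p$exprs <- ds$exprs[perm, ]
  ds_p$sample_ids <- ds$sample_ids[perm]
  for (f in list(score_pearson, score_spearman, score_kendall, score_dcov,
                 score_hoeffding, score_mi)) {
    expect_equal(unclass(f(ds)), unclass(f(ds_p)), tolerance = 1e-12)
  }
  # rdc: seeds key on feature indices, ranks are permutation-equivariant
  # (summation order differs, so agreement is to numerical noise only)
  expect_equal(unclass(score_rdc(ds, seed = 3)),
               unclass(score_rdc(ds_p, seed = 3)), tolerance = 1e-8)
})

test_that("dcov and MI are symmetric in the pair's roles", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(score_dcov(pair_dataset(x, y))[1, 1],
               score_dcov(pair_dataset(y, x))[1, 1], tolerance = 1e-12)
  expect_equal(score_mi(pair_dataset(x, y), bins = 4)[1, 1],
               score_mi(pair_dataset(y, x), bins = 4)[1, 1],
               tolerance = 1e-12)
})

test_that("planted negative regulation separates true from null pairs", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_regulation(n_samples = 300, n_mirna = 4, n_mrna = 30,
                               n_edges = 8, seed = s)
    sm <- score_pearson(sim$dataset)
    truth_idx <- cbind(match(sim$edges$mRNA, rownames(sm)),
                       match(sim$edges$miRNA, colnames(sm)))
    on_edge <- mean(sm[truth_idx])
    off_edge <- mean(sm[-(truth_idx[, 1] + (truth_idx[, 2] - 1) * nrow(sm))])
    on_edge < off_edge
  }, logical(1))
  expect_true(all(hits))
})
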