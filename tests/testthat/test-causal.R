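sem_chain <- function(n, seed) {
  set.seed(seed)
  X <- rnorm(n); Y <- 0.8 * X + rnorm(n); Z <- 0.8 * Y + rnorm(n)
  expr_dataset(cbind(X = X, Y = Y, Z = Z), 1, 2:3)
}

sem_collider <- function(n, seed) {
  set.seed(seed)
  X <- rnorm(n); Y <- rnorm(n); Z <- 0.8 * X + 0.8 * Y + rnorm(n)
  expr_dataset(cbind(X = X, Y = Y, Z = Z), 1:2, 3)
}

test_that("independent features give an empty graph", {
  ds <- make_dataset(n = 1000, n_mir = 1, n_rna = 2, seed = 42)
  g <- pc_stable(ds, alpha = 0.01)
  expect_equal(nrow(g$directed_edges) + nrow(g$undirected_edges), 0)
})

test_that("chain and collider structures are recovered", {
  g <- pc_stable(sem_chain(2000, 7), alpha = 0.01)
  skel <- tidy(g)
  expect_equal(nrow(skel), 2)
  expect_true(all(skel$type == "undirected"))   # chain CPDAG: no collider
  key <- paste(pmin(skel$source, skel$target),
               pmax(skel$source, skel$target))
  expect_setequal(key, c("X Y", "Y Z"))

  g2 <- pc_stable(sem_collider(2000, 7), alpha = 0.01)
  ed <- tidy(g2)
  expect_true(all(ed$type == "directed"))
  expect_setequal(paste(ed$source, ed$target), c("X Z", "Y Z"))
})

test_that("the skeleton is invariant to column permutation", {
  set.seed(15)
  n <- 400
  X1 <- rnorm(n); X2 <- 0.7 * X1 + rnorm(n)
  G1 <- -0.8 * X1 + rnorm(n); G2 <- 0.6 * G1 + rnorm(n)
  G3 <- rnorm(n); G4 <- -0.5 * X2 + 0.5 * G3 + rnorm(n)
  m <- cbind(miR1 = X1, miR2 = X2, G1 = G1, G2 = G2, G3 = G3, G4 = G4)
  ds <- expr_dataset(m, 1:2, 3:6)
  ref <- pc_stable(ds, alpha = 0.01)
  canon <- function(g) {
    list(d = dplyr::arrange(g$directed_edges, source, target),
         u = dplyr::arrange(
           tibble::tibble(a = pmin(g$undirected_edges$source,
                                   g$undirected_edges$target),
                          b = pmax(g$undirected_edges$source,
                                   g$undirected_edges$target)), a, b))
  }
  for (s in 1:10) {
    set.seed(s)
    perm_rna <- sample(4)
    ds_p <- expr_dataset(m[, c(sample(2), 2 + perm_rna)], 1:2, 3:6)
    g_p <- pc_stable(ds_p, alpha = 0.01)
    expect_equal(canon(g_p), canon(ref))
  }
})

test_that("fisher-z partial correlation p-values match regression residuals", {
  set.seed(33)
  n <- 200
  m <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("V", 1:4)))
  m[, 2] <- 0.5 * m[, 1] + 0.5 * m[, 3] + rnorm(n, sd = 0.8)
  C <- cor(m)
  for (S in list(3L, c(3L, 4L))) {
    P <- solve(C[c(1, 2, S), c(1, 2, S)])
    r_impl <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    # brute force: correlate the residuals of both regressions on S
    r1 <- resid(lm(m[, 1] ~ m[, S]))
    r2 <- resid(lm(m[, 2] ~ m[, S]))
    expect_equal(r_impl, cor(r1, r2), tolerance = 1e-10)
  }
})

test_that("ida recovers the planted single-edge effect", {
  set.seed(8)
  n <- 5000
  X <- rnorm(n); Y <- -0.8 * X + rnorm(n)
  ds <- expr_dataset(cbind(miR = X, G = Y), 1, 2)
  g <- pc_stable(ds, alpha = 0.01)
  eff <- ida_effects(ds, g, "miR", "G")
  expect_lt(min(abs(eff + 0.8)), 0.05)
  # on the known directed graph the multiset is a single near -0.8 value
  g_dir <- cpdag_from_edges(c("miR", "G"), directed = cbind("miR", "G"))
  expect_equal(ida_effects(ds, g_dir, "miR", "G"), -0.8, tolerance = 0.05)
  expect_equal(unname(unclass(
    score_ida(ds))[1, 1]), 0)   # undirected edge: conservative min-abs is 0
})

test_that("unreachable mRNAs get exactly zero effects", {
  ds <- make_dataset(n = 200, n_mir = 1, n_rna = 2, seed = 3)
  g_empty <- cpdag_from_edges(colnames(ds$exprs))
  expect_equal(ida_effects(ds, g_empty, "miR1", "G1"), 0)
  sm <- score_ida(make_dataset(n = 1000, n_mir = 1, n_rna = 2, seed = 42))
  expect_true(all(unclass(sm) == 0))
  # min-abs summary keeps the sign of the smallest-magnitude element
  expect_error(ida_effects(ds, g_empty, "nope", "G1"), "not in the CPDAG")
})

test_that("ida_effects matches the exhaustive DAG-extension oracle", {
  # hand-built CPDAGs including an undirected triangle around the miRNA
  set.seed(44)
  n <- 500
  compared <- 0
  for (rep in 1:6) {
    X <- random_sem(p = sample(4:6, 1), n = n, seed = rep)
    ds <- expr_dataset(X, 1, 2:ncol(X))
    g <- pc_stable(ds, alpha = 0.05, max_cond_size = Inf)
    if (!cpdag_is_extendable(g)) next
    compared <- compared + 1
    for (target in colnames(X)[-1]) {
      got <- sort(ida_effects(ds, g, colnames(X)[1], target))
      want <- sort(oracle_ida(g, ds$exprs[, g$nodes], colnames(X)[1],
                              target))
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
  expect_gte(compared, 4)
  # explicit undirected triangle: subsets of the two neighbours are all
  # valid because the triangle keeps them adjacent
  tri <- cpdag_from_edges(c("miR1", "G1", "G2", "G3"),
                          undirected = rbind(c("miR1", "G1"),
                                             c("miR1", "G2"),
                                             c("G1", "G2"),
                                             c("G2", "G3")))
  ds_t <- make_dataset(n = 300, n_mir = 1, n_rna = 3, seed = 5)
  eff <- ida_effects(ds_t, tri, "miR1", "G3")
  expect_equal(length(eff), 4)   # {}, {G1}, {G2}, {G1, G2}
  want <- sort(oracle_ida(tri, ds_t$exprs[, tri$nodes], "miR1", "G3"))
  expect_equal(sort(eff), want, tolerance = 1e-8)
})

test_that("effect estimates concentrate on the true coefficient", {
  errs <- vapply(1:20, function(s) {
    beta <- c(-1, -0.5, 0.5)[(s %% 3) + 1]
    set.seed(s)
    n <- 5000
    X <- rnorm(n); Y <- beta * X + rnorm(n)
    ds <- expr_dataset(cbind(miR = X, G = Y), 1, 2)
    g <- pc_stable(ds, alpha = 0.01)
    eff <- ida_effects(ds, g, "miR", "G")
    min(abs(eff - beta))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the conditioning-size guard raises on tiny samples", {
  # with alpha ~ 1 no edge is ever removed, so on 9 features the level
  # climbs to |S| = 7 where n - |S| - 3 = 0 and the test is undefined
  set.seed(1)
  m <- matrix(rnorm(10 * 9), 10, 9, dimnames = list(NULL, paste0("V", 1:9)))
  ds <- expr_dataset(m, 1:2, 3:9)
  expect_error(pc_stable(ds, alpha = 1 - 1e-12, max_cond_size = 8),
               "undefined")
})
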