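#' @name pairwise-scores
#' @title Pairwise miRNA-mRNA association scores
#'
#' @description
#' Each scorer evaluates every (mRNA, miRNA) pair of a matched expression
#' dataset and returns a [score_matrix()].  Sign-carrying measures
#' (Pearson, Spearman, Kendall) use the `ASC_SIGNED` ordering so that
#' strong negative associations — the signature of miRNA-mediated
#' down-regulation — rank first; non-negative dependence measures
#' (distance correlation, Hoeffding's D, RDC, mutual information, the
#' pseudo-knockout Z-score) use `DESC_VALUE`.
#'
#' Undefined scores (e.g. a zero-variance feature) are stored as 0 with a
#' warning rather than aborting the whole matrix.
#'
#' @param ds An [expr_dataset()], or a CSV path (then `cause`/`effect`
#'   ranges are required, as in `score_pearson("data.csv", 1:35, 36:1189)`).
#' @param cause,effect 1-based inclusive column ranges when `ds` is a path.
#' @return A `mir_scores` matrix (mRNAs x miRNAs).
NULL

as_expr_dataset <- function(ds, cause = NULL, effect = NULL) {
  if (is.character(ds)) {
    if (is.null(cause) || is.null(effect)) {
      stop("cause and effect ranges are required when reading from a file",
           call. = FALSE)
    }
    ds <- read_expression(ds, cause, effect)
  }
  stopifnot(inherits(ds, "expr_dataset"))
  ds
}

check_complete <- function(ds, min_n) {
  if (anyNA(ds$exprs)) {
    stop("missing values present; run impute_normalise() first",
         call. = FALSE)
  }
  if (nrow(ds$exprs) < min_n) {
    stop("need at least ", min_n, " samples", call. = FALSE)
  }
}

# warn once about zero-variance features; their pairs score 0
zero_var_features <- function(ds) {
  sdv <- apply(ds$exprs, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning("zero-variance feature(s) scored 0: ",
            paste(colnames(ds$exprs)[zero], collapse = ", "), call. = FALSE)
  }
  zero
}

cor_scores <- function(ds, method, label) {
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  zv <- zero_var_features(ds)
  r <- suppressWarnings(stats::cor(Y, X, method = method))
  r[!is.finite(r)] <- 0
  r[zv[ds$effect], ] <- 0
  r[, zv[ds$cause]] <- 0
  suppressWarnings(score_matrix(r, label, "ASC_SIGNED"))
}

#' @rdname pairwise-scores
#' @export
score_pearson <- function(ds, cause = NULL, effect = NULL) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 3)
  cor_scores(ds, "pearson", "pearson")
}

#' @rdname pairwise-scores
#' @export
score_spearman <- function(ds, cause = NULL, effect = NULL) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 3)
  cor_scores(ds, "spearman", "spearman")
}

#' @rdname pairwise-scores
#' @export
score_kendall <- function(ds, cause = NULL, effect = NULL) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 3)
  cor_scores(ds, "kendall", "kendall")
}

# double-centred distance matrix of one variable (biased V-statistic form)
dcenter <- function(x) {
  d <- abs(outer(x, x, "-"))
  d - outer(rowMeans(d), rep(1, length(x))) -
    outer(rep(1, length(x)), colMeans(d)) + mean(d)
}

dcor_pair <- function(A, B) {
  n2 <- length(A)
  dcov2 <- sum(A * B) / n2
  vx <- sum(A * A) / n2
  vy <- sum(B * B) / n2
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sqrt(max(0, dcov2) / sqrt(vx * vy))
}

#' @rdname pairwise-scores
#' @export
score_dcov <- function(ds, cause = NULL, effect = NULL) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 4)
  zero_var_features(ds)
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  Ac <- lapply(seq_len(ncol(X)), function(j) dcenter(X[, j]))
  out <- matrix(0, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  for (i in seq_len(ncol(Y))) {
    B <- dcenter(Y[, i])
    for (j in seq_len(ncol(X))) {
      out[i, j] <- dcor_pair(Ac[[j]], B)
    }
  }
  suppressWarnings(score_matrix(out, "dcov", "DESC_VALUE"))
}

midrank <- function(x) rank(x, ties.method = "average")

# Hoeffding's D for one pair via the classical rank formula; ties enter
# through mid-ranks and the 1/4 / 1/2 bivariate-rank convention
hoeffding_pair <- function(x, y) {
  n <- length(x)
  R <- midrank(x); S <- midrank(y)
  lt_x <- outer(x, x, "<"); eq_x <- outer(x, x, "==")
  lt_y <- outer(y, y, "<"); eq_y <- outer(y, y, "==")
  phi <- (lt_x + 0.5 * eq_x) * (lt_y + 0.5 * eq_y)
  diag(phi) <- 0                      # j != i; diagonal would add 1/4 each
  Q <- colSums(phi) + 1               # bivariate rank: self counts once
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' @rdname pairwise-scores
#' @export
score_hoeffding <- function(ds, cause = NULL, effect = NULL) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 5)
  zero_var_features(ds)
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  out <- matrix(0, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(ncol(Y))) {
      out[i, j] <- hoeffding_pair(X[, j], Y[, i])
    }
  }
  out[!is.finite(out)] <- 0
  suppressWarnings(score_matrix(out, "hoeffding", "DESC_VALUE"))
}

# deterministic per-pair seed from (seed, miRNA index, mRNA index); all
# arithmetic stays below 2^53 so the modulus is exact in doubles
pair_seed <- function(seed, j, i) {
  ((abs(seed) %% 100003) * 1000003 + j * 7919 + i * 104729) %% 2147483647
}

# largest canonical correlation between two feature blocks, ridge-
# regularised when a block covariance is singular
max_cancor <- function(U, V, eps = 1e-8) {
  U <- scale(U, scale = FALSE); V <- scale(V, scale = FALSE)
  Cuu <- crossprod(U) / (nrow(U) - 1)
  Cvv <- crossprod(V) / (nrow(V) - 1)
  Cuv <- crossprod(U, V) / (nrow(U) - 1)
  M <- tryCatch(
    solve(Cuu, Cuv) %*% solve(Cvv, t(Cuv)),
    error = function(e) {
      diag(Cuu) <- diag(Cuu) + eps
      diag(Cvv) <- diag(Cvv) + eps
      solve(Cuu, Cuv) %*% solve(Cvv, t(Cuv))
    })
  ev <- eigen(M, only.values = TRUE)$values
  sqrt(min(1, max(0, max(Re(ev)))))
}

rdc_pair <- function(x, y, n_features, scale_par, seed) {
  n <- length(x)
  u <- cbind(rank(x, ties.method = "average") / n, 1)
  v <- cbind(rank(y, ties.method = "average") / n, 1)
  set.seed(seed)
  Wx <- matrix(stats::rnorm(2 * n_features), 2)
  Wy <- matrix(stats::rnorm(2 * n_features), 2)
  Fx <- sin(scale_par / 2 * u %*% Wx)
  Fy <- sin(scale_par / 2 * v %*% Wy)
  max_cancor(Fx, Fy)
}

#' @rdname pairwise-scores
#' @param n_features Number of random sinusoidal projection features.
#' @param scale_par Scale of the random projections applied to the
#'   intercept-augmented copula block.
#' @param seed Integer; each pair derives its own deterministic generator
#'   seed from `(seed, miRNA index, mRNA index)` so projections are
#'   reproducible and uncorrelated across pairs.
#' @export
score_rdc <- function(ds, cause = NULL, effect = NULL, n_features = 20,
                      scale_par = 1 / 6, seed = 1) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 10)
  zero_var_features(ds)
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  out <- matrix(0, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(ncol(Y))) {
      out[i, j] <- rdc_pair(X[, j], Y[, i], n_features, scale_par,
                            pair_seed(seed, j, i))
    }
  }
  out[!is.finite(out)] <- 0
  suppressWarnings(score_matrix(out, "rdc", "DESC_VALUE"))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# equal-frequency discretisation via mid-ranks: permutation invariant,
# ties land together in one bin
ef_bins <- function(x, bins) {
  pmin(bins, pmax(1L, ceiling(bins * midrank(x) / length(x))))
}

mi_pair <- function(bx, by) {
  joint <- table(bx, by) / length(bx)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' @rdname pairwise-scores
#' @param bins Number of equal-frequency bins, or `"auto"` for
#'   `ceiling(n^(1/3))`.
#' @export
score_mi <- function(ds, cause = NULL, effect = NULL, bins = "auto") {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 10)
  n <- nrow(ds$exprs)
  if (identical(bins, "auto")) bins <- ceiling(n^(1 / 3))
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  zero_var_features(ds)
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  bX <- apply(X, 2, ef_bins, bins = bins)
  bY <- apply(Y, 2, ef_bins, bins = bins)
  out <- matrix(0, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(ncol(Y))) {
      out[i, j] <- mi_pair(bX[, j], bY[, i])
    }
  }
  suppressWarnings(score_matrix(out, "mi", "DESC_VALUE"))
}

#' @rdname pairwise-scores
#' @param signed Keep the signed deviation instead of its absolute value
#'   (the default reports |z| so up- and down-shifts both score high).
#' @export
score_zscore <- function(ds, cause = NULL, effect = NULL, signed = FALSE) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 3)
  zv <- zero_var_features(ds)
  X <- cause_matrix(ds); Y <- effect_matrix(ds)
  # pseudo-knockout: the sample where the miRNA is lowest stands in for
  # its knockout condition (first occurrence on ties)
  s_star <- apply(X, 2, which.min)
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  sdv[sdv == 0] <- Inf                  # constant mRNA scores 0
  z <- (t(Y[s_star, , drop = FALSE]) - mu) / sdv
  if (!signed) z <- abs(z)
  colnames(z) <- colnames(X)
  z[, zv[ds$cause]] <- 0
  suppressWarnings(score_matrix(z, "zscore", "DESC_VALUE"))
}
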