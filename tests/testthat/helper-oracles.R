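# Independent brute-force oracles used across the suite.  Every oracle is
# written from the defining formula with explicit loops, deliberately
# sharing no code with the package implementations.

oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx <- dx + (x[i] - xb)^2
    dy <- dy + (y[i] - yb)^2
  }
  num / sqrt(dx * dy)
}

oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- less + (ties + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Kendall tau-b by full pair enumeration with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# distance correlation by explicit double-centring loops (V-statistic)
oracle_dcor <- function(x, y) {
  n <- length(x)
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- abs(x[i] - x[j]); B[i, j] <- abs(y[i] - y[j])
  }
  ctr <- function(M) {
    rm_ <- rowMeans(M); cm <- colMeans(M); gm <- mean(M)
    out <- M
    for (i in seq_len(n)) for (j in seq_len(n)) {
      out[i, j] <- M[i, j] - rm_[i] - cm[j] + gm
    }
    out
  }
  A <- ctr(A); B <- ctr(B)
  v_xy <- mean(A * B); v_x <- mean(A * A); v_y <- mean(B * B)
  if (v_x <= 0 || v_y <= 0) return(0)
  sqrt(max(0, v_xy) / sqrt(v_x * v_y))
}

# Hoeffding's D from the rank definition with explicit counting loops
oracle_hoeffding <- function(x, y) {
  n <- length(x)
  R <- oracle_midrank(x); S <- oracle_midrank(y)
  Q <- numeric(n)
  for (i in seq_len(n)) {
    q <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      fx <- if (x[j] < x[i]) 1 else if (x[j] == x[i]) 0.5 else 0
      fy <- if (y[j] < y[i]) 1 else if (y[j] == y[i]) 0.5 else 0
      q <- q + fx * fy
    }
    Q[i] <- q
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# Benjamini-Hochberg by the literal step-up procedure
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# --- exhaustive DAG-extension oracle for IDA ---------------------------

# v-structures of a DAG given the full skeleton (for nonadjacency)
dag_vstructs <- function(A, skel) {
  p <- nrow(A)
  out <- character()
  for (c_ in seq_len(p)) {
    pa <- which(A[, c_] == 1)
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i < j && !skel[pa[i], pa[j]]) {
        out <- c(out, paste(pa[i], pa[j], c_))
      }
    }
  }
  sort(out)
}

dag_is_acyclic <- function(A) {
  alive <- rep(TRUE, nrow(A))
  repeat {
    if (!any(alive)) return(TRUE)
    indeg <- colSums(A[alive, , drop = FALSE])
    src <- which(alive & indeg == 0)
    if (length(src) == 0) return(FALSE)
    alive[src] <- FALSE
    A[src, ] <- 0
  }
}

dag_descendants <- function(A, x) {
  seen <- rep(FALSE, nrow(A)); seen[x] <- TRUE
  queue <- x
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    nxt <- which(A[a, ] == 1 & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

# A PDAG learned from finite samples is not always a valid CPDAG; the
# parent-set equivalence only holds when at least one consistent DAG
# extension exists.
cpdag_is_extendable <- function(cpdag) {
  G <- cpdag$amat
  p <- nrow(G)
  skel <- (G == 1) | (t(G) == 1)
  A0 <- matrix(0L, p, p)
  A0[G == 1L & t(G) == 0L] <- 1L
  ref_v <- dag_vstructs(A0, skel)
  und <- which(G == 1L & t(G) == 1L & upper.tri(G), arr.ind = TRUE)
  u <- nrow(und)
  for (mask in 0:(2^u - 1)) {
    A <- A0
    if (u > 0) {
      for (e in seq_len(u)) {
        if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0) {
          A[und[e, 1], und[e, 2]] <- 1L
        } else {
          A[und[e, 2], und[e, 1]] <- 1L
        }
      }
    }
    if (dag_is_acyclic(A) && identical(dag_vstructs(A, skel), ref_v)) {
      return(TRUE)
    }
  }
  FALSE
}

# Enumerate every consistent DAG extension of a CPDAG (same skeleton and
# v-structures, directed edges respected), collect the distinct parent
# sets of `x` across extensions, and compute the adjustment-regression
# effect of x on y for each: 0 when y is in the parent set, and 0 for all
# when no extension makes y a descendant of x.
oracle_ida <- function(cpdag, data, xname, yname) {
  nodes <- cpdag$nodes
  G <- cpdag$amat
  p <- length(nodes)
  x <- match(xname, nodes); y <- match(yname, nodes)
  skel <- (G == 1) | (t(G) == 1)
  A0 <- matrix(0L, p, p)
  A0[G == 1L & t(G) == 0L] <- 1L
  ref_v <- dag_vstructs(A0, skel)
  und <- which(G == 1L & t(G) == 1L & upper.tri(G), arr.ind = TRUE)
  u <- nrow(und)
  parent_sets <- list()
  y_ever_descendant <- FALSE
  for (mask in 0:(2^u - 1)) {
    A <- A0
    if (u > 0) {
      for (e in seq_len(u)) {
        if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0) {
          A[und[e, 1], und[e, 2]] <- 1L
        } else {
          A[und[e, 2], und[e, 1]] <- 1L
        }
      }
    }
    if (!dag_is_acyclic(A)) next
    if (!identical(dag_vstructs(A, skel), ref_v)) next
    parent_sets[[length(parent_sets) + 1]] <- sort(which(A[, x] == 1))
    if (y %in% dag_descendants(A, x)) y_ever_descendant <- TRUE
  }
  parent_sets <- unique(parent_sets)
  vapply(parent_sets, function(P) {
    if (y %in% P) return(0)
    if (!y_ever_descendant) return(0)
    dat <- data.frame(yv = data[, y], xv = data[, x])
    if (length(P) > 0) {
      dat <- cbind(dat, data[, P, drop = FALSE])
    }
    unname(stats::coef(stats::lm(yv ~ ., data = dat))["xv"])
  }, numeric(1))
}

# --- common fixtures ----------------------------------------------------

make_dataset <- function(n = 30, n_mir = 2, n_rna = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * (n_mir + n_rna)), n,
              dimnames = list(NULL, c(sprintf("miR%d", seq_len(n_mir)),
                                      sprintf("G%d", seq_len(n_rna)))))
  expr_dataset(m, cause = seq_len(n_mir),
               effect = n_mir + seq_len(n_rna))
}

pair_dataset <- function(x, y) {
  expr_dataset(cbind(miR1 = x, G1 = y), cause = 1, effect = 2)
}

# random linear SEM over a random DAG; returns data + node names
random_sem <- function(p, n, seed, edge_prob = 0.5) {
  set.seed(seed)
  A <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < edge_prob) A[i, j] <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
  }
  perm <- sample(p)                      # random causal order
  X <- matrix(0, n, p)
  for (idx in 1:p) {
    i <- idx
    X[, i] <- X %*% A[, i] + rnorm(n)
  }
  X <- X[, perm]
  colnames(X) <- paste0("V", seq_len(p))
  X
}
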