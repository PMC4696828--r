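#' PC-stable structure learning over all features
#'
#' Learns a completed partially directed acyclic graph (CPDAG) over the
#' joint miRNA + mRNA feature set with the order-independent PC-stable
#' algorithm.  Conditional independence is tested by Fisher's z transform
#' of the sample partial correlation,
#' \eqn{z = \tfrac12 \log\frac{1+\rho}{1-\rho}\sqrt{n - |S| - 3}}, against
#' a two-sided standard-normal reference.  At each level the neighbour
#' sets are frozen before any edge of that level is tested, which makes
#' the skeleton invariant to the ordering of the input columns.
#' Unshielded colliders are oriented from the recorded separating sets,
#' conflicting collider orientations leave the edge undirected, and Meek
#' rules 1-4 are applied to closure.
#'
#' @param ds An [expr_dataset()] (features standardised internally; only
#'   correlations enter the tests).
#' @param alpha Significance level of the conditional-independence tests.
#' @param max_cond_size Largest conditioning-set size explored (the
#'   algorithm is exponential in this; `Inf` removes the cap).
#' @return An object of class `cpdag`: `nodes`, the adjacency code matrix
#'   `amat` (`amat[a, b] == 1` means an edge mark at `b`; both directions
#'   set means undirected), plus `directed_edges` / `undirected_edges`
#'   tibbles.
#' @export
pc_stable <- function(ds, alpha = 0.01, max_cond_size = 3) {
  stopifnot(inherits(ds, "expr_dataset"), alpha > 0, alpha < 1)
  check_complete(ds, 10)
  m <- ds$exprs[, c(ds$cause, ds$effect), drop = FALSE]
  nodes <- colnames(m)
  p <- length(nodes)
  n <- nrow(m)
  C <- stats::cor(m)

  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p)
  for (a in seq_len(p)) sepset[[a]] <- vector("list", p)

  ci_p <- function(a, b, S) {
    if (n - length(S) - 3 <= 0) {
      stop("Fisher-z test undefined: n - |S| - 3 <= 0 at level ",
           length(S), call. = FALSE)
    }
    r <- if (length(S) == 0) {
      C[a, b]
    } else {
      P <- solve(C[c(a, b, S), c(a, b, S)])
      -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    }
    r <- min(1 - 1e-12, max(-1 + 1e-12, r))
    z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(n - length(S) - 3)
    2 * stats::pnorm(-abs(z))
  }

  l <- -1L
  repeat {
    l <- l + 1L
    if (l > max_cond_size) break
    frozen <- lapply(seq_len(p), function(a) which(adj[a, ]))
    if (max(lengths(frozen)) - 1 < l) break
    for (a in seq_len(p)) {
      for (b in frozen[[a]]) {
        if (!adj[a, b]) next
        nbrs <- setdiff(frozen[[a]], b)
        if (length(nbrs) < l) next
        subsets <- safe_combn(nbrs, l)
        for (S in subsets) {
          if (ci_p(a, b, S) > alpha) {
            adj[a, b] <- adj[b, a] <- FALSE
            sepset[[a]][[b]] <- sepset[[b]][[a]] <- S
            break
          }
        }
      }
    }
  }

  # orient unshielded colliders a -> c <- b when c is outside sepset(a, b);
  # conflicting demands cancel (edge stays undirected)
  G <- matrix(0L, p, p)
  G[adj] <- 1L
  want <- matrix(FALSE, p, p)   # want[a, c]: demand a -> c
  for (c_ in seq_len(p)) {
    nb <- which(adj[c_, ])
    if (length(nb) < 2) next
    for (ab in utils::combn(nb, 2, simplify = FALSE)) {
      a <- ab[1]; b <- ab[2]
      if (adj[a, b]) next
      S <- sepset[[a]][[b]]
      if (is.null(S) || !(c_ %in% S)) {
        want[a, c_] <- TRUE
        want[b, c_] <- TRUE
      }
    }
  }
  for (a in seq_len(p)) for (b in seq_len(p)) {
    if (want[a, b] && !want[b, a]) G[b, a] <- 0L
  }

  G <- meek_closure(G)
  new_cpdag(nodes, G)
}

# combn() treats a scalar first argument as seq_len(); always pass a vector
safe_combn <- function(x, m) {
  if (m == 0) return(list(integer(0)))
  if (length(x) < m) return(list())
  if (length(x) == m) return(list(x))
  utils::combn(x, m, simplify = FALSE)
}

# iterate Meek rules 1-4 to a fixed point; G[a,b]=1 & G[b,a]=0 means a->b
meek_closure <- function(G) {
  p <- nrow(G)
  is_dir <- function(a, b) G[a, b] == 1L && G[b, a] == 0L
  is_und <- function(a, b) G[a, b] == 1L && G[b, a] == 1L
  adj <- function(a, b) G[a, b] == 1L || G[b, a] == 1L
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (!is_und(a, b)) next
      orient <- FALSE
      for (c_ in seq_len(p)) {
        if (c_ == a || c_ == b) next
        # R1: c -> a, a - b, c not adjacent b  =>  a -> b
        if (is_dir(c_, a) && !adj(c_, b)) { orient <- TRUE; break }
        # R2: a -> c -> b with a - b  =>  a -> b
        if (is_dir(a, c_) && is_dir(c_, b)) { orient <- TRUE; break }
      }
      if (!orient) {
        # R3: a - c, a - d, c -> b, d -> b, c/d nonadjacent  =>  a -> b
        cand <- which(vapply(seq_len(p), function(k)
          k != a && k != b && is_und(a, k) && is_dir(k, b), logical(1)))
        if (length(cand) >= 2) {
          for (cd in utils::combn(cand, 2, simplify = FALSE)) {
            if (!adj(cd[1], cd[2])) { orient <- TRUE; break }
          }
        }
      }
      if (!orient) {
        # R4: a - c, c -> d, d -> b, c/b nonadjacent, a adjacent d => a -> b
        for (c_ in seq_len(p)) {
          if (c_ == a || c_ == b || !is_und(a, c_) || adj(c_, b)) next
          for (d in seq_len(p)) {
            if (d == a || d == b || d == c_) next
            if (is_dir(c_, d) && is_dir(d, b) && adj(a, d)) {
              orient <- TRUE; break
            }
          }
          if (orient) break
        }
      }
      if (orient) { G[b, a] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  G
}

#' Build a CPDAG from explicit edge lists
#'
#' Mostly useful for studying [ida_effects()] on a known structure
#' without learning it from data.
#'
#' @param nodes Character vector of node names.
#' @param directed Two-column matrix/data frame of `source -> target`
#'   name pairs (may be empty).
#' @param undirected Two-column matrix/data frame of unordered name pairs.
#' @return A `cpdag` object.
#' @export
cpdag_from_edges <- function(nodes, directed = NULL, undirected = NULL) {
  p <- length(nodes)
  G <- matrix(0L, p, p)
  add <- function(pairs, both) {
    if (is.null(pairs) || NROW(pairs) == 0) return()
    pairs <- as.matrix(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- match(pairs[r, 1], nodes); b <- match(pairs[r, 2], nodes)
      if (is.na(a) || is.na(b)) stop("unknown node name", call. = FALSE)
      G[a, b] <<- 1L
      if (both) G[b, a] <<- 1L
    }
  }
  add(directed, both = FALSE)
  add(undirected, both = TRUE)
  new_cpdag(nodes, G)
}

new_cpdag <- function(nodes, G) {
  p <- length(nodes)
  dir <- which(G == 1L & t(G) == 0L, arr.ind = TRUE)
  und <- which(G == 1L & t(G) == 1L & upper.tri(G), arr.ind = TRUE)
  structure(
    list(nodes = nodes, amat = G,
         directed_edges = tibble::tibble(source = nodes[dir[, 1]],
                                         target = nodes[dir[, 2]]),
         undirected_edges = tibble::tibble(source = nodes[und[, 1]],
                                           target = nodes[und[, 2]])),
    class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat(sprintf("<cpdag> %d nodes, %d directed, %d undirected edges\n",
              length(x$nodes), nrow(x$directed_edges),
              nrow(x$undirected_edges)))
  invisible(x)
}

#' Tidy a CPDAG into an edge-list tibble
#'
#' @param x A `cpdag`.
#' @param ... Unused.
#' @return A tibble with columns `source`, `target`, `type`
#'   (directed/undirected).
#' @method tidy cpdag
#' @export
tidy.cpdag <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$directed_edges, type = "directed"),
    dplyr::mutate(x$undirected_edges, type = "undirected"))
}

#' Write a CPDAG edge list to CSV
#'
#' @param cpdag A `cpdag`.
#' @param path Output path (`source,target,type` columns).
#' @export
write_cpdag <- function(cpdag, path) {
  write_csv_lf(as.data.frame(tidy.cpdag(cpdag)), path)
  invisible(path)
}
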