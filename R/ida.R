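#' IDA: possible causal effects of a miRNA on an mRNA
#'
#' Given a CPDAG, the local IDA method enumerates the candidate parent
#' sets of the miRNA: its certain parents (directed into it) plus every
#' subset of its undirected neighbours whose orientation toward the miRNA
#' creates no new collider among the chosen parents (i.e. every chosen
#' neighbour must be adjacent to every other chosen parent).  For each
#' valid parent set \eqn{P}, the possible causal effect is the coefficient
#' of the miRNA in the least-squares regression of the mRNA on
#' \eqn{\{miRNA\} \cup P}; it is 0 when the mRNA lies in \eqn{P}, and 0
#' for all parent sets when the mRNA is not reachable from the miRNA by
#' any semi-directed path (then the effect is zero in every DAG of the
#' equivalence class).  Regressions are run on the expression values as
#' given (not re-standardised), so effects carry the units of the data.
#'
#' @param ds The [expr_dataset()] the CPDAG was learned from.
#' @param cpdag A [pc_stable()] result.
#' @param mirna,mrna Feature names.
#' @return Numeric vector: the multiset of possible causal effects, one
#'   per valid parent set.
#' @export
ida_effects <- function(ds, cpdag, mirna, mrna) {
  stopifnot(inherits(cpdag, "cpdag"))
  x <- match(mirna, cpdag$nodes)
  y <- match(mrna, cpdag$nodes)
  if (is.na(x) || is.na(y)) {
    stop("feature not in the CPDAG: ",
         paste(c(mirna, mrna)[is.na(c(x, y))], collapse = ", "),
         call. = FALSE)
  }
  m <- ds$exprs[, cpdag$nodes, drop = FALSE]
  sets <- valid_parent_sets(cpdag$amat, x)
  reach <- possible_descendants(cpdag$amat, x)
  vapply(sets, function(P) {
    if (y %in% P) return(0)
    if (!(y %in% reach)) return(0)
    adjustment_coef(m, x, y, P)
  }, numeric(1))
}

# all candidate parent sets of node x in the CPDAG: certain parents plus
# each subset S of undirected neighbours with every member of S adjacent
# to every other chosen parent (no new collider at x)
valid_parent_sets <- function(G, x) {
  p <- nrow(G)
  pa <- which(G[, x] == 1L & G[x, ] == 0L)
  sib <- which(G[, x] == 1L & G[x, ] == 1L)
  adj <- (G == 1L) | (t(G) == 1L)
  sets <- list()
  subsets <- unlist(lapply(0:length(sib), function(k)
    safe_combn(sib, k)), recursive = FALSE)
  for (S in subsets) {
    chosen <- c(pa, S)
    ok <- TRUE
    for (s in S) {
      others <- setdiff(chosen, s)
      if (length(others) > 0 && !all(adj[s, others])) { ok <- FALSE; break }
    }
    if (ok) sets[[length(sets) + 1L]] <- sort(chosen)
  }
  sets
}

# nodes reachable from x along semi-directed paths (x -> or undirected)
possible_descendants <- function(G, x) {
  p <- nrow(G)
  # edge a ~> b usable when G[a,b] == 1 (either a->b or a-b)
  seen <- rep(FALSE, p); seen[x] <- TRUE
  queue <- x
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    nxt <- which(G[a, ] == 1L & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

adjustment_coef <- function(m, x, y, P) {
  X <- cbind(1, m[, c(x, P), drop = FALSE])
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    warning("rank-deficient adjustment regression dropped (parent set: ",
            paste(colnames(m)[P], collapse = ","), ")", call. = FALSE)
    return(NA_real_)
  }
  qr.coef(qr_, m[, y])[2]
}

#' IDA causal-effect score matrix
#'
#' Runs [pc_stable()] once over all features, then for every
#' (mRNA, miRNA) pair summarises the [ida_effects()] multiset by its
#' minimum-absolute-value element with the sign preserved — the
#' conservative lower bound on the magnitude of the possible causal
#' effects.  Negative effects (down-regulation) rank first.
#'
#' @inheritParams pairwise-scores
#' @inheritParams pc_stable
#' @return A `mir_scores` matrix, `ASC_SIGNED`.
#' @export
score_ida <- function(ds, cause = NULL, effect = NULL, alpha = 0.01,
                      max_cond_size = 3) {
  ds <- as_expr_dataset(ds, cause, effect)
  cpdag <- pc_stable(ds, alpha = alpha, max_cond_size = max_cond_size)
  m <- ds$exprs[, cpdag$nodes, drop = FALSE]
  mir <- mirna_names(ds); rna <- mrna_names(ds)
  out <- matrix(0, length(rna), length(mir),
                dimnames = list(rna, mir))
  for (j in seq_along(mir)) {
    x <- match(mir[j], cpdag$nodes)
    sets <- valid_parent_sets(cpdag$amat, x)
    reach <- intersect(possible_descendants(cpdag$amat, x),
                       match(rna, cpdag$nodes))
    if (length(reach) == 0) next
    # one multi-response regression per parent set covers every mRNA
    effects <- matrix(NA_real_, length(rna), length(sets))
    for (s in seq_along(sets)) {
      P <- sets[[s]]
      X <- cbind(1, m[, c(x, P), drop = FALSE])
      qr_ <- qr(X)
      if (qr_$rank < ncol(X)) {
        warning("rank-deficient adjustment regression dropped",
                call. = FALSE)
        next
      }
      co <- qr.coef(qr_, m[, rna, drop = FALSE])[2, ]
      co[match(cpdag$nodes[P], rna, nomatch = 0)] <- 0  # mRNA inside P
      effects[, s] <- co
    }
    min_abs <- apply(effects, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(0)
      v[which.min(abs(v))]
    })
    idx_reach <- match(cpdag$nodes[reach], rna)
    out[idx_reach, j] <- min_abs[idx_reach]
  }
  suppressWarnings(score_matrix(out, "ida", "ASC_SIGNED"))
}
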