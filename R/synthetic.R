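#' Simulate a matched expression dataset with planted regulation
#'
#' Emulates a matched miRNA/mRNA expression study: miRNA profiles are iid
#' standard Normal; a planted edge set (allocated as evenly as possible
#' across miRNAs, at most `max_regulators` regulators per mRNA) drives
#' regulated mRNAs through
#' \deqn{mRNA_i = b_i + \sum_j \beta_{ij}\, miR_j + \varepsilon,\qquad
#'   \varepsilon \sim N(0, \sigma^2),}
#' with negative effect sizes \eqn{\beta_{ij}} drawn uniformly from
#' `beta_range` (miRNAs predominantly down-regulate their targets).  A
#' `nonlinear_fraction` of the regulated mRNAs instead passes the linear
#' predictor through a monotone cubic link \eqn{\eta + \eta^3/3}, rescaled
#' to the variance of \eqn{\eta}, so the regulation is monotone-decreasing
#' but non-linear.  Unregulated mRNAs are iid Normal.
#'
#' The generator also emits the two matching ground truths: the planted
#' edge set, and a perturbation table in which each planted edge responds
#' to a simulated two-unit miRNA over-expression
#' (\eqn{lfc = -\beta_{ij}\,\delta + N(0, 0.1)}, \eqn{\delta = 2}) while
#' an equal number of random non-edges drifts by \eqn{N(0, 0.3)}.
#'
#' @param n_samples,n_mirna,n_mrna Problem dimensions.
#' @param n_edges Number of planted regulatory edges.
#' @param beta_range Length-2 numeric, `lo <= hi < 0`.
#' @param noise_sd Residual standard deviation of regulated mRNAs.
#' @param nonlinear_fraction Fraction of regulated mRNAs using the cubic
#'   link.
#' @param max_regulators Cap on regulators per mRNA.
#' @param delta Over-expression shift used for the perturbation table.
#' @param seed Integer seed; the whole triple is reproducible from it.
#' @return A list with `dataset` ([expr_dataset()]), `truth`
#'   ([ground_truth()]), `perturbation` ([perturbation_table()]) and
#'   `edges` (tibble `miRNA`, `mRNA`, `beta`, `nonlinear`).
#' @export
simulate_regulation <- function(n_samples = 300, n_mirna = 20,
                                n_mrna = 500, n_edges = 100,
                                beta_range = c(-1.5, -0.6), noise_sd = 1,
                                nonlinear_fraction = 0,
                                max_regulators = 3, delta = 2, seed = 1) {
  stopifnot(n_mirna >= 1, n_mrna >= 1, n_samples >= 3,
            beta_range[1] <= beta_range[2], beta_range[2] < 0,
            noise_sd > 0, nonlinear_fraction >= 0, nonlinear_fraction <= 1)
  if (n_edges > n_mirna * n_mrna) {
    stop("n_edges exceeds the number of possible pairs", call. = FALSE)
  }
  if (n_edges > n_mrna * max_regulators) {
    stop("edge count infeasible under the regulator cap", call. = FALSE)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  mir_names <- sprintf("miR-%03d", seq_len(n_mirna))
  rna_names <- sprintf("GENE%04d", seq_len(n_mrna))

  # even per-miRNA edge allocation; targets drawn under the regulator cap
  reg_count <- integer(n_mrna)
  per_mir <- rep(n_edges %/% n_mirna, n_mirna)
  extra <- n_edges %% n_mirna
  if (extra > 0) {
    bump <- sample(n_mirna, extra)
    per_mir[bump] <- per_mir[bump] + 1L
  }
  taken <- matrix(FALSE, n_mrna, n_mirna)
  for (j in seq_len(n_mirna)) {
    avail <- which(reg_count < max_regulators & !taken[, j])
    if (length(avail) < per_mir[j]) {
      stop("edge count infeasible under the regulator cap", call. = FALSE)
    }
    tgt <- sample(avail, per_mir[j])
    taken[tgt, j] <- TRUE
    reg_count[tgt] <- reg_count[tgt] + 1L
  }
  idx <- which(taken, arr.ind = TRUE)
  edges <- tibble::tibble(
    miRNA = mir_names[idx[, 2]],
    mRNA = rna_names[idx[, 1]],
    beta = stats::runif(nrow(idx), beta_range[1], beta_range[2]))

  X <- matrix(stats::rnorm(n_samples * n_mirna), n_samples, n_mirna,
              dimnames = list(NULL, mir_names))
  B <- matrix(0, n_mirna, n_mrna)
  B[cbind(idx[, 2], idx[, 1])] <- edges$beta
  eta <- X %*% B                         # linear predictor per mRNA
  regulated <- which(reg_count > 0)
  n_nl <- round(nonlinear_fraction * length(regulated))
  nl <- if (n_nl > 0) sample(regulated, n_nl) else integer(0)
  Y <- matrix(stats::rnorm(n_samples * n_mrna, sd = 1), n_samples, n_mrna,
              dimnames = list(NULL, rna_names))
  for (i in regulated) {
    e <- eta[, i]
    if (i %in% nl) {
      g <- e + e^3 / 3                  # monotone-increasing in eta,
      g <- g * stats::sd(e) / stats::sd(g)  # hence decreasing in the miRNAs
      e <- g
    }
    Y[, i] <- e + stats::rnorm(n_samples, sd = noise_sd)
  }
  m <- cbind(X, Y)
  ds <- expr_dataset(m, cause = seq_len(n_mirna),
                     effect = n_mirna + seq_len(n_mrna))

  truth <- ground_truth(edges$miRNA, edges$mRNA, provenance = "planted")

  non_edges_pool <- which(!taken)
  n_neg <- min(nrow(edges), length(non_edges_pool))
  neg <- arrayInd(sample(non_edges_pool, n_neg), dim(taken))
  pert <- perturbation_table(
    miRNA = c(edges$miRNA, mir_names[neg[, 2]]),
    gene = c(edges$mRNA, rna_names[neg[, 1]]),
    lfc = c(-edges$beta * delta + stats::rnorm(nrow(edges), sd = 0.1),
            stats::rnorm(n_neg, sd = 0.3)))

  edges$nonlinear <- match(edges$mRNA, rna_names) %in% nl
  list(dataset = ds, truth = truth, perturbation = pert, edges = edges)
}

#' Write a simulated study to disk
#'
#' Emits the three CSV formats of the data-IO layer (expression matrix,
#' ground truth, perturbation table) plus a JSON manifest recording the
#' configuration, so a simulated study is a drop-in replacement for a
#' downloaded one.
#'
#' @param sim A [simulate_regulation()] result.
#' @param dir Output directory (created if needed).
#' @param config Optional list echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$dataset, file.path(dir, "expression.csv"))
  write_ground_truth(sim$truth, file.path(dir, "groundtruth.csv"))
  write_perturbation(sim$perturbation, file.path(dir, "perturbation.csv"))
  jsonlite::write_json(
    c(list(n_samples = nrow(sim$dataset$exprs),
           n_mirna = n_mirna(sim$dataset),
           n_mrna = n_mrna(sim$dataset),
           n_edges = nrow(sim$edges)), config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
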