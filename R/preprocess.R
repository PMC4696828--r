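#' Standardise every feature to zero mean and unit variance
#'
#' Each feature column is centred by its sample mean and scaled by its
#' unbiased (n-1 denominator) standard deviation.  Zero-variance columns
#' become all-zero and are reported in a warning; they carry no signal for
#' any downstream scorer.
#'
#' @param ds An [expr_dataset()] with no missing values.
#' @return A standardised `expr_dataset`.
#' @export
standardise <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (anyNA(ds$exprs)) {
    stop("missing values present; run impute_normalise() first",
         call. = FALSE)
  }
  ds$exprs <- standardise_matrix(ds$exprs, warn = TRUE)
  ds
}

standardise_matrix <- function(m, warn = FALSE) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero) && warn) {
    warning("zero-variance features set to all-zero: ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  sdv[zero] <- 1
  out <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  out[, zero] <- 0
  out
}

#' Impute missing values and quantile-normalise across samples
#'
#' Missing cells are filled by k-nearest-neighbour imputation: the
#' neighbours of a sample are the samples closest in Euclidean distance
#' over the features complete in both, and a missing cell takes the mean of
#' that feature over the `k_neighbors` nearest samples in which it is
#' observed (falling back to the feature median when no usable neighbour
#' exists).  Features missing in more than half the samples are dropped
#' with a warning.  The completed matrix is then quantile-normalised across
#' samples: each sample's empirical distribution is mapped onto the mean
#' order-statistic distribution, with ties receiving the mean of the
#' quantile values they span.
#'
#' @param ds An [expr_dataset()].
#' @param k_neighbors Number of nearest samples used per imputation.
#' @return A complete, quantile-normalised `expr_dataset`.
#' @export
impute_normalise <- function(ds, k_neighbors = 10) {
  stopifnot(inherits(ds, "expr_dataset"), k_neighbors >= 1)
  m <- ds$exprs
  frac_missing <- colMeans(is.na(m))
  if (any(frac_missing == 1)) {
    stop("feature(s) with all values missing: ",
         paste(colnames(m)[frac_missing == 1], collapse = ", "),
         call. = FALSE)
  }
  drop <- frac_missing > 0.5
  if (any(drop)) {
    warning("dropping features missing in >50% of samples: ",
            paste(colnames(m)[drop], collapse = ", "), call. = FALSE)
    keep <- which(!drop)
    m <- m[, keep, drop = FALSE]
    # remap cause/effect indices onto the reduced column set
    ds$cause <- match(intersect(ds$cause, keep), keep)
    ds$effect <- match(intersect(ds$effect, keep), keep)
  }
  m <- knn_impute(m, k_neighbors)
  ds$exprs <- quantile_normalise(m)
  ds
}

knn_impute <- function(m, k) {
  if (!anyNA(m)) return(m)
  n <- nrow(m)
  complete_feats <- which(colSums(is.na(m)) == 0)
  d <- if (length(complete_feats) > 0) {
    as.matrix(stats::dist(m[, complete_feats, drop = FALSE]))
  } else NULL
  out <- m
  for (j in which(colSums(is.na(m)) > 0)) {
    obs <- which(!is.na(m[, j]))
    med <- stats::median(m[obs, j])
    for (i in which(is.na(m[, j]))) {
      if (is.null(d) || length(obs) == 0) {
        out[i, j] <- med
        next
      }
      nb <- obs[order(d[i, obs], obs)]
      nb <- nb[seq_len(min(k, length(nb)))]
      out[i, j] <- mean(m[nb, j])
    }
  }
  out
}

# samples in rows: map each row's empirical distribution to the mean
# order-statistic distribution; tied values get the mean of the quantile
# values their positions span
quantile_normalise <- function(m) {
  if (ncol(m) < 2) return(m)
  sorted <- apply(m, 1, sort)            # p x n, each column a sorted sample
  ref <- rowMeans(sorted)                # mean order statistics
  out <- m
  for (i in seq_len(nrow(m))) {
    o <- order(m[i, ])
    vals <- m[i, o]
    grp <- cumsum(!duplicated(vals))     # tie groups in sorted order
    out[i, o] <- stats::ave(ref, grp)    # ties get the mean spanned quantile
  }
  out
}

#' Differential expression by moderated t-statistics
#'
#' Compares two sample groups feature by feature with an empirical-Bayes
#' moderated t-statistic: per-feature pooled within-group variances
#' \eqn{s_g^2} (with \eqn{d_g} degrees of freedom) are shrunk toward a
#' prior \eqn{(d_0, s_0^2)} estimated by method of moments on the observed
#' variances, giving \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 +
#' d_g)} and \eqn{\tilde t_g = (\bar a_g - \bar b_g)/(\tilde s_g
#' \sqrt{1/n_a + 1/n_b})}, referred to a t distribution on \eqn{d_0 + d_g}
#' degrees of freedom.  P-values are adjusted by Benjamini-Hochberg.
#' Selection is by smallest p-value (`top_n`, ties broken by original
#' feature order) or by an adjusted-p threshold (`max_adj_p`).
#'
#' @param group_a,group_b Numeric matrices, samples x features, identical
#'   feature columns, at least two samples each.
#' @param top_n Select the `top_n` smallest-p features.
#' @param max_adj_p Alternatively, select features with adjusted p below
#'   this threshold.
#' @param method `"moderated"` (default) or `"welch"` for a plain Welch
#'   two-sample t-test without variance shrinkage.
#' @return A tibble of class `mir_de` with columns `feature`, `statistic`,
#'   `df`, `p_value`, `adj_p_value`, `selected`.
#' @export
diff_exp <- function(group_a, group_b, top_n = NULL, max_adj_p = NULL,
                     method = c("moderated", "welch")) {
  method <- match.arg(method)
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b) ||
      (!is.null(colnames(group_a)) && !is.null(colnames(group_b)) &&
       !identical(colnames(group_a), colnames(group_b)))) {
    stop("groups must share an identical feature set", call. = FALSE)
  }
  na <- nrow(group_a); nb <- nrow(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples", call. = FALSE)
  features <- colnames(group_a)
  if (is.null(features)) features <- paste0("F", seq_len(ncol(group_a)))

  mean_a <- colMeans(group_a); mean_b <- colMeans(group_b)
  var_a <- apply(group_a, 2, stats::var)
  var_b <- apply(group_b, 2, stats::var)

  if (method == "welch") {
    se <- sqrt(var_a / na + var_b / nb)
    stat <- (mean_a - mean_b) / se
    df <- se^4 / ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  } else {
    dg <- na + nb - 2
    s2 <- ((na - 1) * var_a + (nb - 1) * var_b) / dg
    prior <- moments_prior(s2, dg)
    s2_post <- if (is.finite(prior$d0)) {
      (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
    } else rep(prior$s02, length(s2))
    se <- sqrt(s2_post * (1 / na + 1 / nb))
    stat <- (mean_a - mean_b) / se
    stat[se == 0] <- 0
    df <- rep(prior$d0 + dg, length(stat))
    p <- 2 * stats::pt(-abs(stat), df)
    p[se == 0] <- 1
  }
  adj <- stats::p.adjust(p, method = "BH")

  selected <- rep(FALSE, length(p))
  if (!is.null(top_n)) {
    ord <- order(p, seq_along(p))  # ties broken by original feature order
    selected[ord[seq_len(min(top_n, length(p)))]] <- TRUE
  } else if (!is.null(max_adj_p)) {
    selected <- adj < max_adj_p
  }
  out <- tibble::tibble(feature = features, statistic = unname(stat),
                        df = unname(df), p_value = unname(p),
                        adj_p_value = unname(adj), selected = selected)
  class(out) <- c("mir_de", class(out))
  out
}

# method-of-moments fit of a scaled inverse-chi-square prior to the
# observed within-group variances: on the log scale E[log s^2] and
# Var[log s^2] identify (d0, s0^2) through digamma/trigamma moments
moments_prior <- function(s2, dg) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2)
  # Var(log s_g^2) = trigamma(dg/2) + trigamma(d0/2); solve for d0
  excess <- stats::var(z) - trigamma(dg / 2)
  if (excess <= 0) {
    # variances agree more than sampling noise allows: infinite prior df,
    # prior variance the geometric mean (exact when all variances tie)
    d0 <- Inf
    s02 <- exp(mean(z))
  } else {
    # invert trigamma by monotone bisection
    d0 <- 2 * inv_trigamma(excess)
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

inv_trigamma <- function(y) {
  # trigamma is decreasing on (0, Inf); bracket then bisect
  lo <- 1e-4; hi <- 1e7
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

#' Differential-expression selection of a matched dataset
#'
#' Convenience wrapper mirroring the two-condition workflow: runs
#' [diff_exp()] separately on the miRNA and mRNA blocks of tumour/normal
#' style matrices and returns a matched [expr_dataset()] restricted to the
#' selected features (tumour-group expression), with miRNA columns first.
#'
#' @param mirna_a,mirna_b miRNA expression matrices for the two conditions.
#' @param mrna_a,mrna_b mRNA expression matrices for the two conditions.
#' @param n_mirna,n_mrna Numbers of top features to keep per block.
#' @return An `expr_dataset` of the selected features, group-a expression.
#' @export
diff_exp_dataset <- function(mirna_a, mirna_b, mrna_a, mrna_b,
                             n_mirna, n_mrna) {
  de_mir <- diff_exp(mirna_a, mirna_b, top_n = n_mirna)
  de_rna <- diff_exp(mrna_a, mrna_b, top_n = n_mrna)
  sel_mir <- de_mir$feature[de_mir$selected]
  sel_rna <- de_rna$feature[de_rna$selected]
  m <- cbind(as.matrix(mirna_a)[, sel_mir, drop = FALSE],
             as.matrix(mrna_a)[, sel_rna, drop = FALSE])
  expr_dataset(m, cause = seq_along(sel_mir),
               effect = length(sel_mir) + seq_along(sel_rna))
}
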