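#' Penalised-regression scores (lasso / elastic net)
#'
#' Each mRNA is regressed on all miRNAs jointly and the (standardised-
#' scale) coefficient of each miRNA becomes its score for that mRNA, so a
#' miRNA only scores highly when it explains target variation beyond what
#' the other miRNAs already capture.  The objective per mRNA is
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\left[\alpha\|\beta\|_1 +
#'   \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' with `l1_ratio` \eqn{= \alpha}; `l1_ratio = 1` is the lasso.  Negative
#' coefficients rank first (`ASC_SIGNED`), favouring down-regulation.
#'
#' Predictors (and the response) are standardised internally, so scores
#' are comparable across miRNAs.  `lambda` may be a fixed value (0 solves
#' the unpenalised least-squares limit exactly) or `"cv"` for the k-fold
#' cross-validated minimum-MSE choice with a deterministic, seeded fold
#' assignment (seeded shuffle, then sample index mod folds).
#'
#' @inheritParams pairwise-scores
#' @param l1_ratio Elastic-net mixing parameter in (0, 1].
#' @param lambda Non-negative penalty, or `"cv"`.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return A `mir_scores` matrix (mRNAs x miRNAs), `ASC_SIGNED`.
#' @export
score_regression <- function(ds, cause = NULL, effect = NULL,
                             l1_ratio = 0.5, lambda = "cv", cv_folds = 5,
                             seed = 1) {
  ds <- as_expr_dataset(ds, cause, effect)
  check_complete(ds, 10)
  if (l1_ratio <= 0 || l1_ratio > 1) {
    stop("l1_ratio must be in (0, 1]", call. = FALSE)
  }
  if (is.numeric(lambda) && lambda < 0) {
    stop("lambda must be >= 0", call. = FALSE)
  }
  X <- standardise_matrix(cause_matrix(ds))
  Y <- standardise_matrix(effect_matrix(ds))
  n <- nrow(X)

  foldid <- NULL
  if (identical(lambda, "cv")) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    foldid <- (sample(n) %% cv_folds) + 1L
  }

  out <- matrix(0, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  for (i in seq_len(ncol(Y))) {
    y <- Y[, i]
    if (stats::sd(y) == 0) next   # constant target: all coefficients 0
    if (is.numeric(lambda) && lambda == 0) {
      # unpenalised limit: exact least squares
      fit <- stats::lm.fit(cbind(1, X), y)
      out[i, ] <- fit$coefficients[-1]
    } else if (identical(lambda, "cv")) {
      cv <- glmnet::cv.glmnet(X, y, alpha = l1_ratio, foldid = foldid,
                              standardize = FALSE)
      out[i, ] <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
    } else {
      fit <- glmnet::glmnet(X, y, alpha = l1_ratio, lambda = lambda,
                            standardize = FALSE, thresh = 1e-12)
      out[i, ] <- as.vector(stats::coef(fit, s = lambda))[-1]
    }
  }
  label <- if (l1_ratio == 1) "lasso" else sprintf("elastic(%g)", l1_ratio)
  suppressWarnings(score_matrix(out, label, "ASC_SIGNED"))
}

#' @rdname score_regression
#' @export
score_lasso <- function(ds, cause = NULL, effect = NULL, lambda = "cv",
                        cv_folds = 5, seed = 1) {
  score_regression(ds, cause, effect, l1_ratio = 1, lambda = lambda,
                   cv_folds = cv_folds, seed = seed)
}

#' @rdname score_regression
#' @export
score_elastic <- function(ds, cause = NULL, effect = NULL, l1_ratio = 0.5,
                          lambda = "cv", cv_folds = 5, seed = 1) {
  score_regression(ds, cause, effect, l1_ratio = l1_ratio, lambda = lambda,
                   cv_folds = cv_folds, seed = seed)
}
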