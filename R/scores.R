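#' Score matrices and their ordering conventions
#'
#' Every scoring method fills an mRNAs x miRNAs real matrix: cell (i, j)
#' is the score of the prediction that mRNA i is a target of miRNA j.
#' Because methods disagree on what "better" means, each matrix carries an
#' explicit ordering convention:
#'
#' * `ASC_SIGNED` — smaller (more negative) signed values rank first.
#'   Used by sign-carrying methods (Pearson, Spearman, Kendall, regression
#'   coefficients, IDA effects), reflecting that miRNAs predominantly
#'   down-regulate their targets.
#' * `DESC_VALUE` — larger values rank first (non-negative dependence
#'   measures: distance correlation, Hoeffding's D, RDC, MI, Z-score).
#' * `ASC_RANK` — smaller values rank first (Borda average ranks).
#'
#' @param values Numeric matrix, rows named by mRNAs, columns by miRNAs.
#' @param method_label Short label of the producing method.
#' @param ordering One of `"ASC_SIGNED"`, `"DESC_VALUE"`, `"ASC_RANK"`.
#' @return A `mir_scores` object (a classed matrix with attributes).
#' @export
score_matrix <- function(values, method_label, ordering) {
  ordering <- match.arg(ordering, c("ASC_SIGNED", "DESC_VALUE", "ASC_RANK"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("score matrix needs mRNA row names and miRNA column names",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    warning(sum(!is.finite(values)),
            " undefined score(s) stored as 0", call. = FALSE)
    values[!is.finite(values)] <- 0
  }
  structure(values, method_label = method_label, ordering = ordering,
            class = c("mir_scores", "matrix", "array"))
}

#' @export
print.mir_scores <- function(x, ...) {
  cat(sprintf("<mir_scores> %s: %d mRNAs x %d miRNAs, ordering %s\n",
              attr(x, "method_label"), nrow(x), ncol(x),
              attr(x, "ordering")))
  invisible(x)
}

#' @rdname score_matrix
#' @param sm A `mir_scores` object.
#' @export
score_ordering <- function(sm) attr(sm, "ordering")

#' @rdname score_matrix
#' @export
method_label <- function(sm) attr(sm, "method_label")

#' Tidy a score matrix into long format
#'
#' @param x A `mir_scores` object.
#' @param ... Unused.
#' @return A tibble with columns `miRNA`, `mRNA`, `score`, `method`.
#' @method tidy mir_scores
#' @export
tidy.mir_scores <- function(x, ...) {
  tibble::tibble(
    miRNA = rep(colnames(x), each = nrow(x)),
    mRNA = rep(rownames(x), times = ncol(x)),
    score = as.vector(unclass(x)),
    method = attr(x, "method_label")
  )
}

#' Write / read a score matrix as CSV plus a JSON sidecar
#'
#' The CSV has a first column of mRNA names (`mRNA` header) and one column
#' per miRNA; the sidecar `<path>.json` records the method label and the
#' ordering convention so a round trip preserves both.
#'
#' @param sm A `mir_scores` object.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `mir_scores` (reader).
#' @export
write_scores <- function(sm, path) {
  df <- data.frame(mRNA = rownames(sm), unclass(sm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_lf(df, path)
  jsonlite::write_json(
    list(method_label = attr(sm, "method_label"),
         ordering = attr(sm, "ordering")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  score_matrix(m, method_label = meta$method_label,
               ordering = meta$ordering)
}
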