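#' Convert a score matrix to per-miRNA rankings
#'
#' Realises each method's ordering convention: within every miRNA column
#' the mRNAs are sorted by the matrix's declared ordering (`ASC_SIGNED`
#' ascending signed value, `DESC_VALUE` descending, `ASC_RANK` ascending)
#' and assigned 1-based ranks, ties sharing the mean rank.  Rows are
#' listed with the mRNA name as a deterministic secondary sort key.
#'
#' @param sm A [score_matrix()].
#' @return A tibble of class `mir_ranking` with columns `miRNA`, `mRNA`,
#'   `score`, `rank`; the method label is kept as an attribute.
#' @export
to_ranking <- function(sm) {
  stopifnot(inherits(sm, "mir_scores"))
  ordering <- attr(sm, "ordering")
  key <- if (ordering == "DESC_VALUE") -unclass(sm) else unclass(sm)
  out <- dplyr::bind_rows(lapply(colnames(sm), function(mir) {
    k <- key[, mir]
    keep <- which(!is.na(k))      # drop-mode masking removes pairs
    k <- k[keep]
    r <- rank(k, ties.method = "average")
    ord <- order(k, rownames(sm)[keep])
    tibble::tibble(miRNA = mir, mRNA = rownames(sm)[keep][ord],
                   score = unname(unclass(sm)[keep, mir][ord]),
                   rank = unname(r[ord]))
  }))
  attr(out, "method_label") <- attr(sm, "method_label")
  class(out) <- c("mir_ranking", class(out))
  out
}

ranking_to_rank_matrix <- function(rk) {
  wide <- tidyr::pivot_wider(rk[c("miRNA", "mRNA", "rank")],
                             names_from = "miRNA", values_from = "rank")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$mRNA
  m[order(rownames(m)), , drop = FALSE]   # canonical row order
}

check_ranking_compat <- function(rankings) {
  if (length(rankings) < 2) {
    stop("need at least two rankings to aggregate", call. = FALSE)
  }
  ref_mir <- sort(unique(rankings[[1]]$miRNA))
  ref_rna <- sort(unique(rankings[[1]]$mRNA))
  for (rk in rankings[-1]) {
    if (!identical(sort(unique(rk$miRNA)), ref_mir) ||
        !identical(sort(unique(rk$mRNA)), ref_rna)) {
      stop("rankings cover different miRNA/mRNA name sets", call. = FALSE)
    }
  }
}

as_ranking <- function(x) {
  if (inherits(x, "mir_scores")) to_ranking(x) else x
}

#' Borda rank aggregation of several methods
#'
#' `borda()` averages, per (mRNA, miRNA) pair, the ranks the individual
#' methods assign; the ensemble orders by average rank (smaller is
#' better).  `borda_topk()` first truncates each method's per-miRNA
#' ranking at `k`: every rank strictly greater than `k` is replaced by the
#' maximal rank (the number of mRNAs) before averaging, so only agreement
#' inside the top-k lists counts.  `k >= N` reduces exactly to `borda()`.
#'
#' @param rankings A list of `mir_ranking` tibbles (score matrices are
#'   converted automatically) over identical miRNA and mRNA name sets.
#' @param k Top-list cutoff for `borda_topk()`.
#' @return A `mir_scores` matrix of average ranks, ordering `ASC_RANK`.
#' @export
borda <- function(rankings) {
  rankings <- lapply(rankings, as_ranking)
  check_ranking_compat(rankings)
  mats <- lapply(rankings, ranking_to_rank_matrix)
  ref <- mats[[1]]
  acc <- ref
  for (m in mats[-1]) acc <- acc + m[rownames(ref), colnames(ref)]
  labels <- vapply(rankings, function(r)
    attr(r, "method_label") %||% "?", character(1))
  score_matrix(acc / length(mats),
               paste0("borda(", paste(labels, collapse = "+"), ")"),
               "ASC_RANK")
}

#' @rdname borda
#' @export
borda_topk <- function(rankings, k) {
  stopifnot(k >= 1)
  rankings <- lapply(rankings, as_ranking)
  check_ranking_compat(rankings)
  mats <- lapply(rankings, ranking_to_rank_matrix)
  n_rna <- nrow(mats[[1]])
  ref <- mats[[1]]
  mats <- lapply(mats, function(m) {
    m <- m[rownames(ref), colnames(ref), drop = FALSE]
    m[m > k] <- n_rna
    m
  })
  acc <- Reduce(`+`, mats)
  labels <- vapply(rankings, function(r)
    attr(r, "method_label") %||% "?", character(1))
  score_matrix(acc / length(mats),
               paste0("borda_top", k, "(",
                      paste(labels, collapse = "+"), ")"),
               "ASC_RANK")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingest an externally computed score matrix
#'
#' Reads a CSV score matrix produced by any outside method (first column
#' mRNA names, remaining columns one per miRNA) and aligns it by name to
#' the dataset's feature order so it can be validated and ensembled
#' alongside the built-in methods.  Missing pairs are filled with 0 (with
#' a warning count); unknown feature names are an error.
#'
#' @param ds The [expr_dataset()] defining the expected name sets.
#' @param path CSV file of external scores.
#' @param ordering The ordering convention the external method uses.
#' @param method_label Label recorded on the result.
#' @return A `mir_scores` matrix aligned to `ds`.
#' @export
read_external_result <- function(ds, path, ordering = "DESC_VALUE",
                                 method_label = basename(path)) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!file.exists(path)) {
    stop_mirlens("missing_file", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  ext <- as.matrix(df[, -1, drop = FALSE])
  rownames(ext) <- as.character(df[[1]])
  mir <- mirna_names(ds); rna <- mrna_names(ds)
  alien_col <- setdiff(colnames(ext), mir)
  alien_row <- setdiff(rownames(ext), rna)
  if (length(alien_col) > 0 || length(alien_row) > 0) {
    stop("external result contains unknown feature name(s): ",
         paste(c(alien_col, alien_row), collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, length(rna), length(mir), dimnames = list(rna, mir))
  out[rownames(ext), colnames(ext)] <- ext
  n_missing <- length(rna) * length(mir) - nrow(ext) * ncol(ext)
  if (n_missing > 0) {
    warning(n_missing, " pair(s) absent from the external result ",
            "filled with 0", call. = FALSE)
  }
  score_matrix(out, method_label, ordering)
}

#' Write a ranking as long-format CSV
#'
#' Columns `miRNA,mRNA,score,rank`; the top-k slice of this file is the
#' edge list of the predicted regulatory network.
#'
#' @param rk A `mir_ranking`.
#' @param path Output path.
#' @export
write_ranking <- function(rk, path) {
  write_csv_lf(as.data.frame(rk[c("miRNA", "mRNA", "score", "rank")]), path)
  invisible(path)
}
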