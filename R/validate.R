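#' Extract the top-k predicted targets of each miRNA
#'
#' @param rk A `mir_ranking` (or a [score_matrix()], converted
#'   automatically).
#' @param k Number of targets per miRNA, `1 <= k <=` number of mRNAs.
#'   Ties at the k boundary are broken by mRNA name (lexicographically
#'   smaller included).
#' @return A tibble `miRNA, mRNA, score, rank` of `k` rows per miRNA.
#' @export
extract_topk <- function(rk, k) {
  rk <- as_ranking(rk)
  n_rna <- length(unique(rk$mRNA))
  if (k < 1 || k > n_rna) {
    stop("k must be between 1 and the number of mRNAs (", n_rna, ")",
         call. = FALSE)
  }
  out <- rk |>
    dplyr::group_by(.data$miRNA) |>
    dplyr::arrange(.data$rank, .data$mRNA, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
  attr(out, "method_label") <- attr(rk, "method_label")
  out
}

new_validation <- function(per_mirna, k, method_label, truth_type,
                           uncovered = character()) {
  structure(
    list(per_mirna = per_mirna,
         total = sum(per_mirna$confirmed),
         k = k, method_label = method_label, truth_type = truth_type,
         uncovered = uncovered),
    class = "mir_validation")
}

#' @export
print.mir_validation <- function(x, ...) {
  cat(sprintf(
    "<mir_validation> %s vs %s ground truth, top-%d: %d confirmed\n",
    x$method_label %||% "?", x$truth_type, x$k, x$total))
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `mir_validation`.
#' @param ... Unused.
#' @return The per-miRNA tibble (`miRNA`, `confirmed`, `targets`) with
#'   the totals in attributes.
#' @method tidy mir_validation
#' @export
tidy.mir_validation <- function(x, ...) x$per_mirna

#' Validate top-k predictions against confirmed interactions
#'
#' Counts, per miRNA, how many of its top-k predicted targets appear in
#' the experimentally confirmed interaction set, and totals the counts.
#'
#' @param rk A `mir_ranking` (or score matrix).
#' @param k Top-list size per miRNA.
#' @param truth A [ground_truth()] tibble.
#' @return A `mir_validation` report.
#' @export
validate_confirmed <- function(rk, k, truth) {
  rk <- as_ranking(rk)
  top <- extract_topk(rk, k)
  truth_key <- paste(truth$miRNA, truth$mRNA, sep = "\r")
  per <- top |>
    dplyr::group_by(.data$miRNA) |>
    dplyr::summarise(
      confirmed = sum(paste(.data$miRNA, .data$mRNA, sep = "\r") %in%
                        truth_key),
      targets = list(.data$mRNA[paste(.data$miRNA, .data$mRNA,
                                      sep = "\r") %in% truth_key])) |>
    dplyr::ungroup()
  new_validation(per, k, attr(rk, "method_label"), "confirmed")
}

#' Validate top-k predictions against miRNA perturbation experiments
#'
#' A perturbation experiment compares gene expression with and without a
#' transfected miRNA; genes whose absolute log2 fold-change strictly
#' exceeds `lfc_threshold` are taken as that miRNA's perturbation-derived
#' targets (the default threshold 1.0 means a two-fold change; a gene at
#' exactly the threshold is *not* a target).  miRNAs with no perturbation
#' records contribute 0 and are listed as uncovered.
#'
#' @param rk A `mir_ranking` (or score matrix).
#' @param k Top-list size per miRNA.
#' @param pert A [perturbation_table()].
#' @param lfc_threshold Strict absolute log2 fold-change cutoff (> 0).
#' @return A `mir_validation` report.
#' @export
validate_perturbation <- function(rk, k, pert, lfc_threshold = 1.0) {
  stopifnot(lfc_threshold > 0)
  rk <- as_ranking(rk)
  derived <- pert[abs(pert$lfc) > lfc_threshold, c("miRNA", "gene")]
  names(derived) <- c("miRNA", "mRNA")
  rep_ <- validate_confirmed(rk, k, ground_truth(
    derived$miRNA, derived$mRNA, provenance = "perturbation"))
  rep_$truth_type <- "perturbation"
  rep_$uncovered <- setdiff(unique(rk$miRNA), unique(pert$miRNA))
  rep_
}

#' Validate against both ground-truth types at once
#'
#' @param rk A `mir_ranking` or score matrix.
#' @param k Top-list size per miRNA.
#' @param truth A [ground_truth()] tibble (or CSV path).
#' @param pert A [perturbation_table()] (or CSV path), optional.
#' @param lfc_threshold Passed to [validate_perturbation()].
#' @return A list with elements `confirmed` and (when `pert` is supplied)
#'   `perturbation`, each a `mir_validation`.
#' @export
validate_all <- function(rk, k, truth, pert = NULL, lfc_threshold = 1.0) {
  if (is.character(truth)) truth <- read_ground_truth(truth)
  out <- list(confirmed = validate_confirmed(rk, k, truth))
  if (!is.null(pert)) {
    if (is.character(pert)) pert <- read_perturbation(pert)
    out$perturbation <- validate_perturbation(rk, k, pert, lfc_threshold)
  }
  out
}

#' Compare methods by ranking scores over shared miRNAs
#'
#' Implements the ranking-score comparison: only miRNAs with at least one
#' confirmed target under *every* method are retained; for each retained
#' miRNA the M methods are ranked by confirmed count (descending, ties at
#' the mean rank) and a method at rank r earns `M - r + 1` points; a
#' method's ranking score is its point total over the retained miRNAs.
#' The higher the ranking score, the better the method.  Reports with
#' different ground-truth types are compared separately by the caller.
#'
#' @param reports Named list of `mir_validation` reports, one per method,
#'   sharing the same miRNA set and `k`.
#' @return A tibble of class `mir_comparison` with columns `method`,
#'   `ranking_score`, `total_confirmed`; the retained miRNAs are kept in
#'   the `retained` attribute.
#' @export
compare_methods <- function(reports) {
  stopifnot(length(reports) >= 2)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- vapply(reports, function(r)
      r$method_label %||% "?", character(1))
  }
  ks <- vapply(reports, function(r) r$k, numeric(1))
  if (length(unique(ks)) != 1) {
    stop("reports use different k", call. = FALSE)
  }
  counts <- lapply(reports, function(r)
    stats::setNames(r$per_mirna$confirmed, r$per_mirna$miRNA))
  mirnas <- Reduce(intersect, lapply(counts, names))
  cmat <- sapply(counts, function(cc) cc[mirnas])   # miRNA x method
  if (length(mirnas) == 1) cmat <- matrix(cmat, nrow = 1,
                                          dimnames = list(mirnas,
                                                          names(reports)))
  retained <- mirnas[apply(cmat >= 1, 1, all)]
  M <- length(reports)
  if (length(retained) == 0) {
    message("no miRNA has a confirmed target under every method; ",
            "empty comparison")
    out <- tibble::tibble(method = names(reports), ranking_score = NA_real_,
                          total_confirmed = unname(colSums(cmat)))
  } else {
    sub <- cmat[retained, , drop = FALSE]
    pts <- t(apply(sub, 1, function(v) {
      r <- rank(-v, ties.method = "average")
      M - r + 1
    }))
    if (length(retained) == 1) pts <- matrix(pts, nrow = 1)
    out <- tibble::tibble(method = names(reports),
                          ranking_score = unname(colSums(pts)),
                          total_confirmed = unname(colSums(sub)))
  }
  attr(out, "retained") <- retained
  attr(out, "k") <- ks[[1]]
  class(out) <- c("mir_comparison", class(out))
  out
}

#' Write a validation report to JSON and CSV
#'
#' @param report A `mir_validation`.
#' @param path_json,path_csv Output paths (either may be `NULL`).
#' @export
write_validation <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(method = report$method_label, truth_type = report$truth_type,
           k = report$k, total_confirmed = report$total,
           uncovered = report$uncovered,
           per_mirna = data.frame(
             miRNA = report$per_mirna$miRNA,
             confirmed = report$per_mirna$confirmed)),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    write_csv_lf(data.frame(miRNA = report$per_mirna$miRNA,
                            confirmed = report$per_mirna$confirmed),
                 path_csv)
  }
  invisible(report)
}

#' Totals table over several top-k cutoffs
#'
#' The summary printed for the standard validation figure: total
#' confirmed interactions at each k, per ground-truth type.
#'
#' @param rk A `mir_ranking` or score matrix.
#' @param truth A [ground_truth()] tibble.
#' @param pert Optional [perturbation_table()].
#' @param ks Top-k cutoffs to tabulate.
#' @param lfc_threshold Passed to [validate_perturbation()].
#' @return A tibble `k`, `truth_type`, `confirmed`.
#' @export
validation_curve <- function(rk, truth, pert = NULL,
                             ks = c(100, 200, 300, 400),
                             lfc_threshold = 1.0) {
  rk <- as_ranking(rk)
  ks <- ks[ks <= length(unique(rk$mRNA))]
  dplyr::bind_rows(lapply(ks, function(k) {
    v <- validate_all(rk, k, truth, pert, lfc_threshold)
    dplyr::bind_rows(lapply(names(v), function(type) {
      tibble::tibble(k = k, truth_type = type, confirmed = v[[type]]$total)
    }))
  }))
}
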