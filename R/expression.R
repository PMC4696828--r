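#' Construct a matched miRNA/mRNA expression dataset
#'
#' Bundles an expression matrix (samples in rows, features in columns,
#' log2 scale assumed) with the column index sets identifying the putative
#' regulators (miRNAs, the "cause" block) and their potential targets
#' (mRNAs, the "effect" block).
#'
#' @param exprs Numeric matrix, samples x features, with column names
#'   (feature names). Row names are used as sample IDs when present.
#' @param cause Integer vector of miRNA column indices (1-based).
#' @param effect Integer vector of mRNA column indices (1-based).
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `expr_dataset` with elements `exprs`,
#'   `sample_ids`, `cause`, `effect`.
#' @examples
#' m <- matrix(rnorm(30), 5, 6,
#'             dimnames = list(NULL, c("miR1", "miR2", paste0("G", 1:4))))
#' ds <- expr_dataset(m, cause = 1:2, effect = 3:6)
#' n_mirna(ds); n_mrna(ds)
#' @export
expr_dataset <- function(exprs, cause, effect, sample_ids = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  cause <- as.integer(cause)
  effect <- as.integer(effect)
  if (is.null(colnames(exprs))) {
    stop("expression matrix must have column (feature) names", call. = FALSE)
  }
  if (length(intersect(cause, effect)) > 0) {
    stop_mirlens("overlapping_ranges",
                 "cause and effect column ranges overlap")
  }
  if (length(cause) < 1 || length(effect) < 1) {
    stop("need at least one miRNA and one mRNA column", call. = FALSE)
  }
  if (max(c(cause, effect)) > ncol(exprs) || min(c(cause, effect)) < 1) {
    stop("cause/effect indices outside the column range", call. = FALSE)
  }
  if (nrow(exprs) < 3) {
    stop("need at least 3 samples", call. = FALSE)
  }
  nm <- colnames(exprs)[c(cause, effect)]
  if (anyDuplicated(nm)) {
    stop("duplicate feature names within the dataset: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(exprs)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(exprs)))
  }
  rownames(exprs) <- sample_ids
  structure(
    list(exprs = exprs, sample_ids = sample_ids,
         cause = cause, effect = effect),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d samples, %d miRNAs, %d mRNAs (%d columns total)\n",
    nrow(x$exprs), length(x$cause), length(x$effect), ncol(x$exprs)))
  if (anyNA(x$exprs)) {
    cat(sprintf("  missing values: %d\n", sum(is.na(x$exprs))))
  }
  invisible(x)
}

#' @rdname expr_dataset
#' @param ds An `expr_dataset`.
#' @export
n_mirna <- function(ds) length(ds$cause)

#' @rdname expr_dataset
#' @export
n_mrna <- function(ds) length(ds$effect)

#' @rdname expr_dataset
#' @export
mirna_names <- function(ds) colnames(ds$exprs)[ds$cause]

#' @rdname expr_dataset
#' @export
mrna_names <- function(ds) colnames(ds$exprs)[ds$effect]

# miRNA block (samples x miRNAs) and mRNA block (samples x mRNAs)
cause_matrix <- function(ds) ds$exprs[, ds$cause, drop = FALSE]
effect_matrix <- function(ds) ds$exprs[, ds$effect, drop = FALSE]

#' Tidy an expression dataset into long format
#'
#' @param x An `expr_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `feature`, `role`
#'   (miRNA/mRNA), `expression`.
#' @method tidy expr_dataset
#' @export
tidy.expr_dataset <- function(x, ...) {
  role <- rep(NA_character_, ncol(x$exprs))
  role[x$cause] <- "miRNA"
  role[x$effect] <- "mRNA"
  keep <- c(x$cause, x$effect)
  tibble::tibble(
    sample = rep(x$sample_ids, times = length(keep)),
    feature = rep(colnames(x$exprs)[keep], each = nrow(x$exprs)),
    role = rep(role[keep], each = nrow(x$exprs)),
    expression = as.vector(x$exprs[, keep])
  )
}

# error helper: distinct, named conditions per the IO contract
stop_mirlens <- function(class, msg) {
  stop(structure(
    class = c(paste0("mirlens_", class), "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

MISSING_TOKENS <- c("", "na", "nan")

#' Read a matched expression CSV
#'
#' The file must have a header row of feature names and one row per sample;
#' miRNA columns come first, then mRNA columns, identified by 1-based
#' inclusive ranges (e.g. `cause = 1:35, effect = 36:1189`).  An optional
#' leading sample-ID column is auto-detected when its header is `"Sample"`
#' (case-insensitive) or its values are non-numeric; ranges refer to the
#' data columns after its removal.  The tokens `""`, `"NA"`, `"NaN"`
#' (case-insensitive) are read as missing.
#'
#' @param path Path to the CSV file.
#' @param cause 1-based inclusive miRNA column range.
#' @param effect 1-based inclusive mRNA column range.
#' @return An [expr_dataset()].
#' @export
read_expression <- function(path, cause, effect) {
  if (!file.exists(path)) {
    stop_mirlens("missing_file", paste0("file not found: ", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  if (ncol(raw) >= 2) {
    first <- raw[[1]]
    cleaned <- trimws(first)
    is_num <- suppressWarnings(!is.na(as.numeric(cleaned)) |
                                 tolower(cleaned) %in% MISSING_TOKENS)
    if (tolower(names(raw)[1]) == "sample" || !all(is_num)) {
      sample_ids <- first
      raw <- raw[, -1, drop = FALSE]
    } else sample_ids <- NULL
  } else sample_ids <- NULL
  if (length(intersect(cause, effect)) > 0) {
    stop_mirlens("overlapping_ranges",
                 "cause and effect column ranges overlap")
  }
  if (max(c(cause, effect)) > ncol(raw)) {
    stop("cause/effect range exceeds the file's column count", call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- trimws(raw[[j]])
    miss <- tolower(v) %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(v))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop_mirlens("non_numeric_cell", sprintf(
        "non-numeric value '%s' in column '%s', row %d",
        v[which(bad)[1]], names(raw)[j], which(bad)[1]))
    }
    num[miss] <- NA_real_
    mat[, j] <- num
  }
  expr_dataset(mat, cause = cause, effect = effect, sample_ids = sample_ids)
}

#' Write an expression dataset to CSV
#'
#' Emits RFC-4180 CSV (UTF-8, LF line endings) with a leading `Sample`
#' column and feature-name header, the format [read_expression()] reads.
#'
#' @param ds An `expr_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  df <- data.frame(Sample = ds$sample_ids, ds$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_lf(df, path)
  invisible(path)
}

# deterministic RFC-4180 writer (LF endings regardless of platform)
write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  quote_field <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "NA"
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  header <- paste(quote_field(names(df)), collapse = ",")
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- formatC(col, digits = 15, format = "g")
      out[is.na(col)] <- "NA"
      out
    } else quote_field(col)
  })
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), con, sep = "\n")
}

#' Read a confirmed-interaction ground-truth CSV
#'
#' Two columns with header `miRNA,mRNA`; one experimentally confirmed
#' miRNA-target pair per row.  Duplicate pairs are dropped (set semantics).
#'
#' @param path Path to the CSV file.
#' @param provenance Free-text label recorded on the result.
#' @return A tibble of class `mir_truth` with columns `miRNA`, `mRNA`.
#' @export
read_ground_truth <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) {
    stop_mirlens("missing_file", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("ground-truth CSV needs two columns", call. = FALSE)
  ground_truth(df[[1]], df[[2]], provenance = provenance)
}

#' @rdname read_ground_truth
#' @param miRNA,mRNA Character vectors of pair members.
#' @export
ground_truth <- function(miRNA, mRNA, provenance = "user") {
  stopifnot(length(miRNA) == length(mRNA))
  ok <- nzchar(miRNA) & nzchar(mRNA)
  if (!all(ok)) stop("ground-truth names must be non-empty", call. = FALSE)
  out <- dplyr::distinct(tibble::tibble(miRNA = as.character(miRNA),
                                        mRNA = as.character(mRNA)))
  attr(out, "provenance") <- provenance
  class(out) <- c("mir_truth", class(out))
  out
}

#' Read a miRNA perturbation table
#'
#' Three columns with header `miRNA,gene,lfc`: the log2 fold-change of each
#' gene between transfected and control conditions of a miRNA perturbation
#' experiment.  Duplicate (miRNA, gene) pairs keep the first record, with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `mir_perturbation` with columns `miRNA`,
#'   `gene`, `lfc`.
#' @export
read_perturbation <- function(path) {
  if (!file.exists(path)) {
    stop_mirlens("missing_file", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3) stop("perturbation CSV needs three columns", call. = FALSE)
  perturbation_table(as.character(df[[1]]), as.character(df[[2]]),
                     as.numeric(df[[3]]))
}

#' @rdname read_perturbation
#' @param miRNA,gene Character vectors; `lfc` numeric log2 fold-changes.
#' @param lfc Numeric log2 fold-changes.
#' @export
perturbation_table <- function(miRNA, gene, lfc) {
  stopifnot(length(miRNA) == length(gene), length(gene) == length(lfc))
  if (any(!is.finite(lfc))) stop("lfc values must be finite", call. = FALSE)
  out <- tibble::tibble(miRNA = miRNA, gene = gene, lfc = lfc)
  dup <- duplicated(out[c("miRNA", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (miRNA, gene) perturbation records; ",
            "keeping first occurrence", call. = FALSE)
    out <- out[!dup, ]
  }
  class(out) <- c("mir_perturbation", class(out))
  out
}

#' @rdname read_ground_truth
#' @param truth A `mir_truth` tibble.
#' @export
write_ground_truth <- function(truth, path) {
  write_csv_lf(data.frame(miRNA = truth$miRNA, mRNA = truth$mRNA), path)
  invisible(path)
}

#' @rdname read_perturbation
#' @param pert A `mir_perturbation` tibble.
#' @export
write_perturbation <- function(pert, path) {
  write_csv_lf(data.frame(miRNA = pert$miRNA, gene = pert$gene,
                          lfc = pert$lfc), path)
  invisible(path)
}
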