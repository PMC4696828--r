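#' Mask a score matrix by sequence-based target information
#'
#' Restricts expression-based predictions to (miRNA, mRNA) pairs that are
#' also supported by sequence-based target prediction (e.g. an exported
#' TargetScan pair list) or CLIP-derived binding evidence.  Pairs absent
#' from the binding list are set to the ordering-specific null score —
#' 0 for `ASC_SIGNED` and `DESC_VALUE`, the number of mRNAs for
#' `ASC_RANK` — so an unsupported pair can never enter a top-k list ahead
#' of a supported pair with a non-null score.  Masking is idempotent.
#'
#' @param sm A [score_matrix()].
#' @param binding A `mir_truth`-shaped tibble of supported
#'   (`miRNA`, `mRNA`) pairs, in the same name space as `sm`.
#' @param mode `"null"` (default) scores unsupported pairs at the null
#'   value; `"drop"` marks them `NA` so [to_ranking()] and top-k
#'   extraction omit them entirely.
#' @return The masked `mir_scores` matrix (same ordering).
#' @export
apply_target_mask <- function(sm, binding, mode = c("null", "drop")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sm, "mir_scores"))
  binding <- binding[binding$miRNA %in% colnames(sm) &
                       binding$mRNA %in% rownames(sm), , drop = FALSE]
  if (nrow(binding) == 0) {
    stop("empty binding list: the mask would null every pair",
         call. = FALSE)
  }
  supported <- matrix(FALSE, nrow(sm), ncol(sm),
                      dimnames = dimnames(sm))
  supported[cbind(binding$mRNA, binding$miRNA)] <- TRUE
  null_score <- if (attr(sm, "ordering") == "ASC_RANK") nrow(sm) else 0
  out <- unclass(sm)
  out[!supported] <- if (mode == "drop") NA_real_ else null_score
  masked <- structure(out, method_label = paste0(attr(sm, "method_label"),
                                                 "+mask"),
                      ordering = attr(sm, "ordering"),
                      class = class(sm))
  masked
}
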