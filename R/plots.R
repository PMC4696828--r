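#' Plot a score matrix as a heatmap
#'
#' @param object A [score_matrix()].
#' @param top_n Show only the `top_n` mRNAs with the strongest best score
#'   (full matrices of thousands of rows do not render usefully).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_scores
#' @export
autoplot.mir_scores <- function(object, top_n = 50, ...) {
  df <- tidy.mir_scores(object)
  best <- df |>
    dplyr::group_by(.data$mRNA) |>
    dplyr::summarise(strength = max(abs(.data$score))) |>
    dplyr::arrange(dplyr::desc(.data$strength)) |>
    dplyr::slice_head(n = top_n)
  df <- dplyr::filter(df, .data$mRNA %in% best$mRNA)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$miRNA, y = .data$mRNA,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(title = attr(object, "method_label"),
                  subtitle = paste("ordering:", attr(object, "ordering")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot validation totals across top-k cutoffs
#'
#' @param curve A [validation_curve()] tibble (optionally with an extra
#'   `method` column to facet several methods).
#' @return A ggplot object.
#' @export
plot_validation_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = factor(.data$k),
                                           y = .data$confirmed,
                                           fill = .data$truth_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "top-k targets per miRNA",
                  y = "confirmed interactions", fill = "ground truth") +
    ggplot2::theme_minimal()
  if ("method" %in% names(curve)) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}

#' Plot a method comparison by ranking score
#'
#' @param object A [compare_methods()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_comparison
#' @export
autoplot.mir_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ranking_score,
    y = stats::reorder(.data$method, .data$ranking_score))) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(y = NULL, x = "ranking score (higher is better)") +
    ggplot2::theme_minimal()
}
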