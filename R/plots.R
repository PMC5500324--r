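#' Plot the filter cascade of a screen result
#'
#' Bar chart of the gene count surviving each stage of the specificity
#' cascade, in cascade order.
#'
#' @param object A `screen_result` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  counts <- object$stage_counts
  counts$stage <- factor(counts$stage, levels = counts$stage)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Specificity filter cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an enrichment result
#'
#' Horizontal bars of -log10 p per tested term, significant terms
#' highlighted.
#'
#' @param object An `enrich_result` from [enrich()].
#' @param max_terms Show at most this many top terms (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrich_result <- function(object, max_terms = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), max_terms)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$term_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "FDR significant") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  title = "GO term over-representation") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#'
#' Scatter of the first two principal components, optionally coloured by
#' sample group.
#'
#' @param object A `pca_qc` object from [pca_qc()].
#' @param annotations Optional sample annotation tibble to colour points by
#'   `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_qc <- function(object, annotations = NULL, ...) {
  df <- object$scores
  frac <- object$variance_fraction
  if (!is.null(annotations)) {
    ann <- sample_annotation(annotations)
    df <- dplyr::left_join(df, ann[, c("sample_id", "group")], by = "sample_id")
  } else {
    df$group <- "sample"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * frac[1L]),
      y = sprintf("PC2 (%.0f%%)", 100 * frac[2L]),
      title = "Sample PCA"
    ) +
    ggplot2::theme_minimal()
}
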