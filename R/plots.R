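#' Heatmap of a clustered expression matrix
#'
#' Tile heatmap of per-gene z-scores with genes in dendrogram leaf order
#' and the fill scale clipped to the display range (stored z-scores are
#' untouched).
#'
#' @param object A `clustered_matrix` from [zscore_and_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clustered_matrix
#' @export
autoplot.clustered_matrix <- function(object, ...) {
  long <- tidy(object) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(object$leaf_order)),
           sample_id = factor(.data$sample_id,
                              levels = object$samples$sample_id))
  clip <- object$display_clip
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", limits = clip,
                                  oob = scales::squish,
                                  name = "z-score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of a tissue-detection Venn partition
#'
#' @param object A `venn_partition` from [venn_partition()].
#' @param drop_empty Drop regions with zero genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, drop_empty = TRUE, ...) {
  df <- tidy(object)
  if (drop_empty) df <- filter(df, .data$n_genes > 0L)
  df <- mutate(df, region = factor(.data$region, levels = object$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#4d90c4") +
    ggplot2::labs(x = "tissue set", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of peak-tissue counts
#'
#' @param object A `peak_summary` from [peak_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_summary
#' @export
autoplot.peak_summary <- function(object, ...) {
  df <- mutate(object$tissue_counts,
               tissue = factor(.data$tissue, levels = TISSUE_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#66a182") +
    ggplot2::labs(x = "peak tissue", y = "genes") +
    ggplot2::theme_minimal()
}
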