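#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a differential expression result
#'
#' @param object A `de_result` from [nb_lrt_test()].
#' @param alpha DEG threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, alpha = 0.01, ...) {
  df <- as_tibble(unclass(object))
  df$deg <- df$p <= alpha
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
                 colour = .data$deg)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change",
                  y = expression(-log[10] ~ p),
                  title = sprintf("%s vs %s", attr(object, "group_a"),
                                  attr(object, "group_b")))
}

#' Bar chart of rescue class counts
#'
#' @param rescue A `rescue_table` from [classify_rescue()].
#' @return A ggplot.
#' @export
plot_rescue_summary <- function(rescue) {
  df <- dplyr::count(as_tibble(unclass(rescue)), .data$label)
  ggplot(df, aes(x = .data$label, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes", title = "Rescue classification")
}

#' Stacked bar chart of subcluster composition per group
#'
#' @param proportions Output of [subcluster_proportions()].
#' @return A ggplot.
#' @export
plot_subcluster_proportions <- function(proportions) {
  ggplot(proportions,
         aes(x = .data$group, y = .data$percent,
             fill = factor(.data$subcluster, levels = microglia_subclusters()))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of microglia", fill = "subcluster")
}

#' Bar chart of lineage activation scores
#'
#' @param scores Output of [activation_score()].
#' @return A ggplot; the dashed line marks parity (100%).
#' @export
plot_activation_scores <- function(scores) {
  ggplot(scores, aes(x = .data$group, y = .data$score, fill = .data$lineage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "activation score (% of resting)")
}

#' Heatmap of a panel z-score matrix
#'
#' @param z Output of [zscore_matrix()].
#' @return A ggplot tile heatmap (genes x samples).
#' @export
plot_zscore_heatmap <- function(z) {
  long <- tidyr::pivot_longer(z, -"gene", names_to = "sample_id",
                              values_to = "z")
  ggplot(long, aes(x = .data$sample_id, y = .data$gene, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}
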