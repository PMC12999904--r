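# ggplot2 views of the main result types.

#' Boxplots of a structure metric across groups
#'
#' @param metrics Tibble from [structure_metrics()] with an added grouping
#'   column.
#' @param metric Column name to plot (default "gene_length").
#' @param group Grouping column name (default "species").
#' @return A ggplot.
#' @export
plot_structure <- function(metrics, metric = "gene_length", group = "species") {
  ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data[[group]], y = .data[[metric]], fill = .data[[group]]
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of orthogroup category gene counts
#'
#' @param categories Tibble from [classify_oggs()].
#' @return A ggplot.
#' @export
plot_category_counts <- function(categories) {
  df <- categories |>
    group_by(.data$category) |>
    summarise(genes = sum(.data$n_genes), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$genes,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$genes), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Heatmap of element proportions (optionally column-scaled)
#'
#' @param props Wide tibble from [element_proportions()] (or its z-scored
#'   counterpart).
#' @return A ggplot tile map.
#' @export
plot_element_heatmap <- function(props) {
  long <- tidyr::pivot_longer(props, -"group", names_to = "element",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$element, y = .data$group,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ka/Ks means per cluster or orthogroup
#'
#' @param summary Tibble from [aggregate_kaks()] (`ogg` or `cluster` table).
#' @param x Column for the x axis ("cluster" or "ogg_id").
#' @return A ggplot.
#' @export
plot_kaks <- function(summary, x = if ("cluster" %in% names(summary)) "cluster" else "ogg_id") {
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data[[x]]), y = .data$mean_omega)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = x, y = "mean Ka/Ks") +
    ggplot2::theme_minimal()
}

#' qPCR fold-change time course
#'
#' @param folds Tibble from [ddct()].
#' @return A ggplot with SD error bars.
#' @export
plot_qpcr <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$timepoint, y = .data$fold_mean,
                                      colour = .data$gene_id, group = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_mean - .data$fold_sd,
                                        ymax = .data$fold_mean + .data$fold_sd),
                           width = 0.3) +
    ggplot2::labs(x = "hours after treatment", y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}
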