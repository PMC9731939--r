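# ggplot2 views of the result objects.

#' Plot mean permutation importances of one graph
#'
#' @param object A `cd_importance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd_importance <- function(object, ...) {
  df <- dplyr::arrange(object$importance, .data$importance)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean permutation importance (held-out accuracy drop)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-graph importance distributions across features
#'
#' Box plots of the per-graph mean permutation importances, ordered by
#' median importance — the distributions the pairwise Wilcoxon tests
#' compare.
#'
#' @param distributions Long tibble `graph`, `feature`, `importance` from
#'   [collect_distributions()].
#' @return A ggplot.
#' @export
plot_importance_distributions <- function(distributions) {
  ord <- distributions |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = median(.data$importance), .groups = "drop") |>
    dplyr::arrange(.data$m)
  df <- dplyr::mutate(distributions,
                      feature = factor(.data$feature, levels = ord$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "black", size = 1.6) +
    ggplot2::labs(x = "permutation importance (per graph)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a coassociation matrix
#'
#' Nodes are ordered by a hierarchical clustering of coassociation
#' distance so stable communities appear as blocks.
#'
#' @param object A `cd_coassoc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd_coassoc <- function(object, ...) {
  C <- object$C
  ord <- stats::hclust(stats::as.dist(1 - C))$order
  df <- tidyr::expand_grid(j = seq_len(ncol(C)), i = seq_len(nrow(C)))
  df$c <- as.vector(C[ord, ord])  # column-major: i varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "C", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
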