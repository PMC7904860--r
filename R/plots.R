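#' Violin/jitter plot of strand-bias distributions
#'
#' The canonical view of maintenance activity: symmetric maintenance gives a
#' tight distribution around f = 0.5, loss of maintenance a bimodal spread
#' toward 0 and 1.
#'
#' @param records Record tibble from [compute_bias()].
#' @param by Facet/x-axis variable: `"context"`, `"allele"`, or `"cell"`.
#' @param drop_masked Exclude masked (low-coverage) records.
#' @return A ggplot object.
#' @export
plot_strand_bias <- function(records, by = c("context", "allele", "cell"),
                             drop_masked = TRUE) {
  by <- match.arg(by)
  x <- records
  if (drop_masked) x <- filter(x, !.data$masked)
  ggplot2::ggplot(x, ggplot2::aes(x = .data[[by]], y = .data$f)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "red3") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "strand bias f", x = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a strand-bias matrix
#'
#' Cells (rows, ordered by their mean |f - 0.5|) by regions, coloured by f;
#' masked entries are blank.
#'
#' @param object A [build_bias_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strand_bias_matrix <- function(object, ...) {
  long <- generics::tidy(object)
  ord <- long |>
    group_by(.data$cell) |>
    summarise(dev = mean(abs(.data$f - 0.5), na.rm = TRUE)) |>
    arrange(.data$dev)
  long$cell <- factor(long$cell, levels = ord$cell)
  ggplot2::ggplot(filter(long, !.data$masked),
                  ggplot2::aes(x = .data$region, y = .data$cell, fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "blue3", mid = "grey95",
                                  high = "red3", limits = c(0, 1)) +
    ggplot2::labs(x = "region", y = "cell", fill = "f") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Silhouette curve of a clustering result
#'
#' @param object A [cluster_cells()] result.
#' @param ... Unused.
#' @return A ggplot object showing mean silhouette width per candidate k with
#'   the chosen k marked.
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "k", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}
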