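#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a strand-bias matrix into long format
#'
#' @param x A [build_bias_matrix()] result.
#' @param ... Unused.
#' @return Tibble `cell`, `region`, `f`, `masked`.
#' @export
tidy.strand_bias_matrix <- function(x, ...) {
  tibble(
    cell = rep(rownames(x$f), times = ncol(x$f)),
    region = rep(colnames(x$f), each = nrow(x$f)),
    f = as.vector(x$f),
    masked = as.vector(x$mask)
  )
}

#' @export
glance.strand_bias_matrix <- function(x, ...) {
  tibble(n_cells = nrow(x$f), n_regions = ncol(x$f),
         frac_masked = mean(x$mask), context = x$context)
}

#' Tidy cluster labels
#'
#' @param x A [cluster_cells()] result.
#' @param ... Unused.
#' @return Tibble `cell`, `cluster`.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(cell = names(x$labels), cluster = as.integer(x$labels))
}

#' @export
glance.cluster_result <- function(x, ...) {
  chosen <- x$silhouette$mean_silhouette[x$silhouette$k == x$k]
  tibble(k = x$k, mean_silhouette = if (length(chosen)) chosen else NA_real_,
         n_cells = length(x$labels), seed = x$seed)
}
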