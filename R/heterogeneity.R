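#' Build a cells-by-regions strand-bias matrix
#'
#' Spreads strand-bias records into a numeric matrix of f values (rows =
#' cells, columns = regions) with a missingness mask covering masked
#' (low-coverage) and absent records. Cells with fewer than `min_regions`
#' unmasked entries are dropped.
#'
#' @param records Record tibble from [compute_bias()], restricted to one
#'   context.
#' @param min_regions Minimum unmasked regions per retained cell.
#' @param split_allele If `TRUE`, regions are split by allele
#'   (`region|allele`); otherwise records from different alleles must not
#'   collide on one region.
#' @return An object of class `strand_bias_matrix`: list with `f` (matrix),
#'   `mask` (logical matrix, `TRUE` = missing/masked), `context`,
#'   `dropped_cells`.
#' @export
build_bias_matrix <- function(records, min_regions = 3, split_allele = FALSE) {
  if (nrow(records) == 0L) abort("no records to build a matrix from")
  ctx <- unique(records$context)
  if (length(ctx) != 1L) abort("records must come from a single context")
  x <- records
  x$col <- if (split_allele) paste0(x$region, "|", x$allele) else x$region
  if (!split_allele && anyDuplicated(x[, c("cell", "col")]))
    abort("multiple records per (cell, region); use split_allele = TRUE or filter by allele")
  x$f_use <- if_else(x$masked, NA_real_, x$f)
  wide <- x |>
    select("cell", "col", "f_use") |>
    tidyr::pivot_wider(names_from = "col", values_from = "f_use")
  f <- as.matrix(wide[, -1, drop = FALSE])
  rownames(f) <- wide$cell
  ord <- order(colnames(f))
  f <- f[, ord, drop = FALSE]
  ok <- rowSums(!is.na(f)) >= min_regions
  dropped <- rownames(f)[!ok]
  if (length(dropped) > 0)
    inform(sprintf("dropping %d cell(s) with < %d usable regions", length(dropped), min_regions))
  f <- f[ok, , drop = FALSE]
  if (nrow(f) == 0L) abort("no cells retained after the min_regions filter")
  structure(list(f = f, mask = is.na(f), context = ctx, dropped_cells = dropped),
            class = "strand_bias_matrix")
}

#' @export
print.strand_bias_matrix <- function(x, ...) {
  cat(sprintf("<strand_bias_matrix> %d cells x %d regions (%s), %.1f%% masked\n",
              nrow(x$f), ncol(x$f), x$context, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
as.matrix.strand_bias_matrix <- function(x, ...) x$f

# Impute masked entries with the maintenance expectation f = 0.5
# (used only for k-means / silhouette distances).
impute_bias <- function(mat, value = 0.5) {
  f <- mat$f
  f[mat$mask] <- value
  f
}

#' Cluster cells on their strand-bias profiles
#'
#' Runs k-means (best of `n_restarts`) on the 0.5-imputed strand-bias matrix
#' for each candidate k and picks the k with the highest mean silhouette
#' width. When no k >= 2 yields a defined silhouette (e.g. all cells
#' identical), a single cluster is reported.
#'
#' @param mat A [build_bias_matrix()] result.
#' @param k_range Candidate cluster counts.
#' @param n_restarts k-means restarts per k.
#' @param seed Integer seed; identical seeds give identical labels.
#' @return An object of class `cluster_result`: list with chosen `k`,
#'   `labels` (named integer vector in 1..k), `silhouette` (tibble of k and
#'   mean silhouette width), `seed`, `n_restarts`.
#' @export
cluster_cells <- function(mat, k_range = 1:5, n_restarts = 10, seed = 1) {
  stopifnot(inherits(mat, "strand_bias_matrix"))
  x <- impute_bias(mat)
  if (max(k_range) > nrow(x)) abort("k_range exceeds the number of cells")
  d <- stats::dist(x)
  withr::local_seed(derive_seed(seed, 7000L))
  fits <- list()
  sil <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k < 2) next
    km <- tryCatch(stats::kmeans(x, centers = k, nstart = n_restarts),
                   error = function(e) NULL)
    if (is.null(km)) next
    sw <- cluster::silhouette(km$cluster, d)
    msw <- mean(sw[, "sil_width"])
    if (is.finite(msw)) {
      sil[i] <- msw
      fits[[as.character(k)]] <- km
    }
  }
  if (all(is.na(sil))) {
    k_best <- 1L
    labels <- stats::setNames(rep(1L, nrow(x)), rownames(x))
  } else {
    k_best <- k_range[which.max(sil)]
    labels <- stats::setNames(fits[[as.character(k_best)]]$cluster, rownames(x))
  }
  structure(list(k = as.integer(k_best), labels = labels,
                 silhouette = tibble(k = as.integer(k_range), mean_silhouette = sil),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d over %d cells (seed %d)\n",
              x$k, length(x$labels), x$seed))
  print(x$silhouette)
  invisible(x)
}

#' Per-cell strand-bias variance
#'
#' Sample variance of the unmasked f values of each cell; a high variance
#' marks cells whose chromosomes swing between plus- and minus-dominated
#' methylation (loss of maintenance), a near-zero variance marks symmetric
#' maintenance.
#'
#' @param mat A [build_bias_matrix()] result.
#' @param cells Optional subset of cell names.
#' @return Tibble `cell`, `n_regions`, `variance` (`NA` with fewer than 2
#'   unmasked regions).
#' @export
cell_bias_variance <- function(mat, cells = NULL) {
  stopifnot(inherits(mat, "strand_bias_matrix"))
  f <- mat$f
  if (!is.null(cells)) f <- f[rownames(f) %in% cells, , drop = FALSE]
  tibble(
    cell = rownames(f),
    n_regions = as.integer(rowSums(!is.na(f))),
    variance = unname(apply(f, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::var(v) else NA_real_
    }))
  )
}

#' Detect sister-cell pairs by anti-correlated strand bias
#'
#' Sister cells inherit complementary template strands, so their
#' chromosome-wise strand-bias vectors mirror each other around 0.5. Pairs
#' are reported when the Pearson correlation of their f vectors over shared
#' unmasked regions is at most `r_threshold` and each cell is the other's
#' most-negative partner (mutual best); remaining conflicts are resolved
#' greedily by ascending r. The result is a matching: no cell appears twice.
#'
#' @param mat A [build_bias_matrix()] result.
#' @param r_threshold Maximum (most positive) correlation for a reported pair.
#' @param min_shared Minimum shared unmasked regions per pair.
#' @return Tibble `cell_a`, `cell_b`, `r`, `n_shared`, sorted by r; empty when
#'   no pair qualifies.
#' @export
find_sisters <- function(mat, r_threshold = -0.8, min_shared = 3) {
  stopifnot(inherits(mat, "strand_bias_matrix"))
  if (r_threshold >= 0) abort("r_threshold must be negative")
  f <- mat$f
  cells <- rownames(f)
  n <- nrow(f)
  empty <- tibble(cell_a = character(), cell_b = character(),
                  r = double(), n_shared = integer())
  if (n < 2) return(empty)
  pairs <- list(); k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !is.na(f[i, ]) & !is.na(f[j, ])
      if (sum(shared) < min_shared) next
      vi <- f[i, shared]; vj <- f[j, shared]
      if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next
      k <- k + 1L
      pairs[[k]] <- tibble(cell_a = cells[i], cell_b = cells[j],
                           r = stats::cor(vi, vj), n_shared = sum(shared))
    }
  }
  if (k == 0L) return(empty)
  all_r <- bind_rows(pairs)
  # most-negative partner per cell, over all pairs with a defined r
  best <- bind_rows(
    all_r |> select(cell = "cell_a", partner = "cell_b", "r"),
    all_r |> select(cell = "cell_b", partner = "cell_a", "r")
  ) |>
    group_by(.data$cell) |>
    dplyr::slice_min(.data$r, n = 1, with_ties = FALSE) |>
    ungroup()
  bp <- stats::setNames(best$partner, best$cell)
  cand <- all_r |>
    filter(.data$r <= r_threshold,
           bp[.data$cell_a] == .data$cell_b,
           bp[.data$cell_b] == .data$cell_a) |>
    arrange(.data$r)
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$cell_a[i] %in% used) && !(cand$cell_b[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$cell_a[i], cand$cell_b[i])
    }
  }
  cand[keep, ]
}
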