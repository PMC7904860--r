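#' Binomial likelihood-ratio test for strand bias
#'
#' Tests whether plus/minus 5mC counts depart from the symmetric null
#' p = 0.5. The statistic is the binomial G-test,
#' `G = 2 * (n_plus * log(f/0.5) + n_minus * log((1-f)/0.5))` with
#' `f = n_plus / (n_plus + n_minus)` (zero-count terms contribute 0), referred
#' to the upper tail of a chi-squared distribution with 1 df. Vectorized.
#'
#' @param n_plus,n_minus Non-negative counts (recycled to common length);
#'   each pair must have a positive total.
#' @return P-values in (0, 1], symmetric in `(n_plus, n_minus)`.
#' @examples
#' lrt_strand_bias(5, 5)    # 1
#' lrt_strand_bias(10, 0)   # ~1.97e-4
#' @export
lrt_strand_bias <- function(n_plus, n_minus) {
  n <- n_plus + n_minus
  if (any(n < 1)) abort("each (n_plus, n_minus) pair must have a positive total")
  f <- n_plus / n
  term <- function(k, p) if_else(k > 0, k * log(p / 0.5), 0)
  g <- 2 * (term(n_plus, f) + term(n_minus, 1 - f))
  pmin(stats::pchisq(g, df = 1, lower.tail = FALSE), 1)
}

# P-value used in the record pipeline: exact binomial below `exact_below`
# total sites (chi-squared asymptotics are poor there), G-test otherwise.
strand_bias_pvalue <- function(n_plus, n_minus, exact_below = 25) {
  n <- n_plus + n_minus
  p <- rep(NA_real_, length(n))
  big <- n >= exact_below
  if (any(big)) p[big] <- lrt_strand_bias(n_plus[big], n_minus[big])
  small <- !big & n > 0
  if (any(small)) {
    p[small] <- mapply(function(k, nn) stats::binom.test(k, nn, 0.5)$p.value,
                       n_plus[small], n[small])
  }
  p
}

#' Compute strand-bias records per cell and region
#'
#' Partitions deduplicated calls into regions (whole chromosomes or fixed-size
#' bins), counts plus- and minus-strand 5mC sites per
#' (cell, region, allele, context), and reports the strand bias
#' `f = n_plus / (n_plus + n_minus)` with a departure-from-0.5 p-value.
#' Records with fewer than `min_sites` sites are masked (f still reported)
#' rather than dropped, so downstream matrices keep their shape.
#'
#' @param calls Deduplicated calls from [dedup()].
#' @param group `"chromosome"` or `"bin"`.
#' @param bin_size Bin width in bp when `group = "bin"`; binning is 0-based
#'   half-open with the last partial bin kept.
#' @param context Optional context filter (e.g. `"CpG"`).
#' @param allele Optional allele filter (e.g. `"allele1"`).
#' @param min_sites Minimum sites for an unmasked record (default 50).
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble of records: `cell`, `region`, `chrom`, `start0`, `end0`,
#'   `allele`, `context`, `n_plus`, `n_minus`, `n_total`, `f`, `pvalue`,
#'   `significant`, `masked`. Counts partition the (filtered) calls exactly.
#' @export
compute_bias <- function(calls, group = c("chromosome", "bin"), bin_size = NULL,
                         context = NULL, allele = NULL, min_sites = 50,
                         alpha = 0.05) {
  group <- match.arg(group)
  x <- calls
  if (!is.null(context)) x <- filter(x, .data$context %in% !!context)
  if (!is.null(allele)) x <- filter(x, .data$allele %in% !!allele)
  if (nrow(x) == 0L) {
    warn("no calls after filtering; returning an empty record table")
    return(tibble(cell = character(), region = character(), chrom = character(),
                  start0 = integer(), end0 = integer(), allele = character(),
                  context = character(), n_plus = integer(), n_minus = integer(),
                  n_total = integer(), f = double(), pvalue = double(),
                  significant = logical(), masked = logical()))
  }
  if (group == "bin") {
    if (is.null(bin_size) || bin_size < 1) abort("`bin_size` is required when group = \"bin\"")
    start0 <- as.integer(floor(x$pos0 / bin_size) * bin_size)
    x <- mutate(x, start0 = start0, end0 = start0 + as.integer(bin_size),
                region = sprintf("%s:%d-%d", .data$chrom, .data$start0, .data$end0))
  } else {
    x <- mutate(x, start0 = NA_integer_, end0 = NA_integer_, region = .data$chrom)
  }
  rec <- x |>
    group_by(.data$cell, .data$region, .data$chrom, .data$start0, .data$end0,
             .data$allele, .data$context) |>
    summarise(n_plus = sum(.data$strand == "+"),
              n_minus = sum(.data$strand == "-"),
              .groups = "drop") |>
    mutate(n_total = .data$n_plus + .data$n_minus,
           f = if_else(.data$n_total > 0, .data$n_plus / .data$n_total, NA_real_),
           pvalue = strand_bias_pvalue(.data$n_plus, .data$n_minus),
           masked = .data$n_total < min_sites,
           significant = !.data$masked & !is.na(.data$pvalue) & .data$pvalue < alpha) |>
    arrange(.data$cell, .data$chrom, .data$start0, .data$allele, .data$context) |>
    select("cell", "region", "chrom", "start0", "end0", "allele", "context",
           "n_plus", "n_minus", "n_total", "f", "pvalue", "significant", "masked")
  rec
}

#' Per-cell correlation between plus- and minus-strand 5mC levels
#'
#' Computes, for each cell, the Pearson correlation between the plus-strand
#' and minus-strand 5mC counts across regions. Cells in which maintenance
#' methylation is intact have symmetric dyads and correlate strongly; cells
#' that lost maintenance show uncorrelated (or anti-correlated) strand counts.
#'
#' @param calls Deduplicated calls.
#' @inheritParams compute_bias
#' @param min_sites Regions with fewer total sites are excluded (default 1,
#'   i.e. regions with any signal are used).
#' @return Tibble `cell`, `context`, `r`, `n_regions`; `r` is `NA` (flagged by
#'   `ok = FALSE`) when fewer than 3 usable regions remain or a strand vector
#'   is constant.
#' @export
plus_minus_correlation <- function(calls, group = c("chromosome", "bin"),
                                   bin_size = NULL, context = NULL,
                                   allele = NULL, min_sites = 1) {
  rec <- compute_bias(calls, group = group, bin_size = bin_size,
                      context = context, allele = allele,
                      min_sites = min_sites, alpha = 0.05)
  rec |>
    filter(!.data$masked) |>
    group_by(.data$cell, .data$context) |>
    summarise(
      n_regions = dplyr::n(),
      r = if (dplyr::n() >= 3 && stats::sd(.data$n_plus) > 0 &&
              stats::sd(.data$n_minus) > 0)
        stats::cor(.data$n_plus, .data$n_minus) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(ok = !is.na(.data$r)) |>
    select("cell", "context", "r", "n_regions", "ok")
}
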