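#' Classify CpG dyads from hairpin-bisulfite observations
#'
#' Counts symmetrically methylated ((T,T)), hemi-methylated ((T,F)/(F,T)) and
#' unmethylated ((F,F)) dyads and the derived fractions. The fraction of
#' symmetric dyads among methylated ones is the direct read-out of
#' maintenance-methylation activity.
#'
#' @param observations Tibble with logical columns `top_methylated` and
#'   `bottom_methylated` (post-bisulfite interpretation: unconverted C =
#'   methylated), e.g. from [simulate_hairpin()].
#' @return One-row tibble of class `dyad_summary`: `n_symmetric`, `n_hemi`,
#'   `n_unmethylated`, `n_total`, `frac_symmetric_of_methylated`
#'   (`n_symmetric / (n_symmetric + n_hemi)`), `frac_symmetric_of_all`.
#' @export
classify_dyads <- function(observations) {
  need <- c("top_methylated", "bottom_methylated")
  if (!all(need %in% names(observations)))
    abort("observations must have columns top_methylated and bottom_methylated")
  t_ <- observations$top_methylated
  b_ <- observations$bottom_methylated
  if (anyNA(t_) || anyNA(b_)) abort("both methylation flags must be defined for every dyad")
  n_sym <- sum(t_ & b_)
  n_hemi <- sum(xor(t_, b_))
  n_un <- sum(!t_ & !b_)
  n <- length(t_)
  stopifnot(n_sym + n_hemi + n_un == n)
  out <- tibble(
    n_symmetric = n_sym,
    n_hemi = n_hemi,
    n_unmethylated = n_un,
    n_total = n,
    frac_symmetric_of_methylated =
      if (n_sym + n_hemi > 0) n_sym / (n_sym + n_hemi) else NA_real_,
    frac_symmetric_of_all = if (n > 0) n_sym / n else NA_real_
  )
  class(out) <- c("dyad_summary", class(out))
  out
}

# Method-of-moments inversion of the per-strand flip model: each strand's
# read-out flips with probability e independently, so observed class
# probabilities are M %*% true class probabilities.
conversion_matrix <- function(e) {
  matrix(c((1 - e)^2,       e * (1 - e),       e^2,
           2 * e * (1 - e), (1 - e)^2 + e^2,   2 * e * (1 - e),
           e^2,             e * (1 - e),       (1 - e)^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("sym", "hemi", "un"), c("sym", "hemi", "un")))
}

estimate_maintenance <- function(counts, conv_err) {
  obs <- counts / sum(counts)
  est <- solve(conversion_matrix(conv_err), obs)
  clipped <- any(est < 0 | est > 1)
  est <- pmax(est, 0)
  denom <- est["sym"] + est["hemi"]
  list(value = if (denom > 0) unname(est["sym"] / denom) else NA_real_,
       clipped = clipped)
}

#' Correct the symmetric-dyad fraction for bisulfite conversion error
#'
#' Inverts the expected 2x2 read-out confusion (each strand flipped
#' independently with probability `conv_err`) by method of moments on the
#' (symmetric, hemi, unmethylated) class proportions, then reports the
#' corrected maintenance fraction `sym / (sym + hemi)` clipped to [0, 1],
#' with a seeded multinomial bootstrap confidence interval. With
#' `conv_err = 0` the corrected estimate equals the raw fraction.
#'
#' @param summary A [classify_dyads()] result (or any list/tibble with
#'   `n_symmetric`, `n_hemi`, `n_unmethylated`).
#' @param conv_err Per-strand flip probability (< 0.5).
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (percentile interval).
#' @return One-row tibble: `raw_frac`, `corrected_maintenance`, `ci_lower`,
#'   `ci_upper`, `conv_err`, `n_total`.
#' @export
correct_conversion <- function(summary, conv_err, n_boot = 1000, seed = 1,
                               conf_level = 0.95) {
  if (conv_err < 0 || conv_err >= 0.5) abort("conv_err must be in [0, 0.5)")
  counts <- c(sym = summary$n_symmetric[1], hemi = summary$n_hemi[1],
              un = summary$n_unmethylated[1])
  n <- sum(counts)
  raw <- if (counts["sym"] + counts["hemi"] > 0)
    unname(counts["sym"] / (counts["sym"] + counts["hemi"])) else NA_real_
  if (counts["sym"] + counts["hemi"] == 0) {
    warn("no methylated dyads observed; maintenance fraction is undefined")
    return(tibble(raw_frac = NA_real_, corrected_maintenance = NA_real_,
                  ci_lower = NA_real_, ci_upper = NA_real_,
                  conv_err = conv_err, n_total = n))
  }
  est <- estimate_maintenance(counts, conv_err)
  if (est$clipped)
    warn("moment inversion left [0, 1]; estimate clipped")
  withr::local_seed(derive_seed(seed, 8000L))
  boots <- stats::rmultinom(n_boot, size = n, prob = counts / n)
  boot_vals <- apply(boots, 2L, function(cc) {
    names(cc) <- names(counts)
    estimate_maintenance(cc, conv_err)$value
  })
  ci <- stats::quantile(boot_vals, probs = c((1 - conf_level) / 2,
                                             1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  value <- min(max(est$value, 0), 1)
  tibble(raw_frac = raw,
         corrected_maintenance = value,
         ci_lower = min(ci[1], value),
         ci_upper = max(ci[2], value),
         conv_err = conv_err,
         n_total = n)
}
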