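#' Simulate hairpin-bisulfite CpG dyad read pairs
#'
#' Each dyad's true (top, bottom) methylation is drawn from the maintenance
#' model: the parental strand (top or bottom with equal probability) is
#' methylated with probability `m_parent`; the daughter strand is methylated
#' with probability `e_maint` given a methylated parent. Bisulfite read-out
#' then flips each strand's observed methylation status independently with
#' probability `conv_err`, modelling failed and over-conversion.
#'
#' @param n_dyads Number of CpG dyads.
#' @param m_parent Parental-strand methylation probability.
#' @param e_maint Maintenance efficiency.
#' @param conv_err Per-strand read-out flip probability.
#' @param seed Integer seed.
#' @return Tibble with `dyad_id`, observed `top_methylated` /
#'   `bottom_methylated`, and the pre-error truth (`true_top`, `true_bottom`).
#' @export
simulate_hairpin <- function(n_dyads, m_parent = 0.8, e_maint = 0.95,
                             conv_err = 0.005, seed = 1) {
  assert_prob(m_parent, "m_parent"); assert_prob(e_maint, "e_maint")
  assert_prob(conv_err, "conv_err")
  if (n_dyads < 1) abort("n_dyads must be >= 1")
  withr::local_seed(derive_seed(seed, 4000L))
  parent_is_top <- stats::runif(n_dyads) < 0.5
  parent_meth <- stats::runif(n_dyads) < m_parent
  daughter_meth <- parent_meth & (stats::runif(n_dyads) < e_maint)
  true_top <- if_else(parent_is_top, parent_meth, daughter_meth)
  true_bottom <- if_else(parent_is_top, daughter_meth, parent_meth)
  flip_top <- stats::runif(n_dyads) < conv_err
  flip_bottom <- stats::runif(n_dyads) < conv_err
  tibble(
    dyad_id = seq_len(n_dyads),
    top_methylated = xor(true_top, flip_top),
    bottom_methylated = xor(true_bottom, flip_bottom),
    true_top = true_top,
    true_bottom = true_bottom
  )
}
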