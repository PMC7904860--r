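#' Simulation parameters for the methylome/library model
#'
#' Bundles the parameters of the maintenance/de-novo methylation model and of
#' library construction. Defaults describe a methylation-maintaining somatic
#' cell: most CpG dyads methylated on the parental strand, near-complete
#' DNMT1 copying to the daughter strand, low de novo CpA methylation, a small
#' 5hmC fraction, and moderate per-site capture with PCR duplication.
#'
#' @param m_parent Probability a CpG dyad is methylated on the parental strand.
#' @param e_maint Maintenance efficiency: probability the daughter-strand
#'   cytosine of a CpG dyad is methylated given the parental strand is. This is
#'   the DNMT1 activity axis; `e_maint = 1` gives fully symmetric dyads,
#'   `e_maint = 0` the knockout/passive-demethylation regime.
#' @param d_cpa De novo CpA methylation probability, independent per strand
#'   (DNMT3a/b activity; not copied by maintenance).
#' @param h_frac Fraction of methylated sites carrying 5hmC instead of 5mC.
#'   Glucosylation makes these invisible to the digest.
#' @param capture_eff Probability a true 5mC site in a recognizable context
#'   yields a sequenced fragment.
#' @param dup_rate Mean number of extra PCR/IVT duplicate reads per molecule
#'   (Poisson).
#' @param conv_err Hairpin-bisulfite conversion error: probability a strand's
#'   methylation status is read flipped.
#' @param n_cells Number of cells to simulate.
#' @param barcodes Character vector of 8-nt cell barcodes; defaults to
#'   [default_barcodes()] of length `n_cells`.
#' @param seed Integer seed for all stochastic stages.
#' @return An object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(m_parent = 0.8, e_maint = 0.95, d_cpa = 0.02,
                       h_frac = 0.05, capture_eff = 0.3, dup_rate = 0.5,
                       conv_err = 0.005, n_cells = 1,
                       barcodes = NULL, seed = 1) {
  for (nm in c("m_parent", "e_maint", "d_cpa", "h_frac", "capture_eff", "conv_err"))
    assert_prob(get(nm), nm)
  if (dup_rate < 0) abort("dup_rate must be non-negative")
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (is.null(barcodes)) barcodes <- default_barcodes(n_cells, seed = seed)
  if (n_cells > length(barcodes)) abort("n_cells must not exceed the number of barcodes")
  if (any(nchar(barcodes) != 8L)) abort("cell barcodes must be 8 nt")
  if (anyDuplicated(barcodes)) abort("cell barcodes must be unique")
  structure(list(m_parent = m_parent, e_maint = e_maint, d_cpa = d_cpa,
                 h_frac = h_frac, capture_eff = capture_eff,
                 dup_rate = dup_rate, conv_err = conv_err,
                 n_cells = as.integer(n_cells), barcodes = barcodes,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate well-separated cell barcodes
#'
#' Greedily samples random 8-nt barcodes keeping pairwise Hamming distance at
#' least `min_dist`, so single sequencing errors cannot switch cells.
#'
#' @param n Number of barcodes.
#' @param width Barcode width in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @return Character vector of `n` barcodes.
#' @export
default_barcodes <- function(n, width = 8, min_dist = 3, seed = 1) {
  withr::local_seed(derive_seed(seed, 1L))
  chosen <- character(0)
  tries <- 0L
  while (length(chosen) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    ok <- length(chosen) == 0L ||
      all(hamming_matrix(cand, chosen) >= min_dist)
    if (ok) chosen <- c(chosen, cand)
    tries <- tries + 1L
    if (tries > 100000L) abort("could not place the requested number of barcodes")
  }
  chosen
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> m_parent=%.2f e_maint=%.2f d_cpa=%.3f h_frac=%.2f ",
                     "capture_eff=%.2f dup_rate=%.2f conv_err=%.3f n_cells=%d seed=%d\n"),
              x$m_parent, x$e_maint, x$d_cpa, x$h_frac, x$capture_eff,
              x$dup_rate, x$conv_err, x$n_cells, x$seed))
  invisible(x)
}
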