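# Shared fixture builders. Everything is generated in code; no files.

# 200-bp chromosome that is A/T everywhere except one planted site.
# plus_site: "CGTA" at pos0 100 -> plus-strand C at 100, CpG context, R (A) at +3.
# minus_site: "TACG" at pos0 100 -> minus-strand C at 103 (plus G), CpG context
#   on the minus strand, recognition base A at minus +3.
toy_genome <- function(kind = c("plus", "minus", "plus_cnnt"), seed = 1) {
  kind <- match.arg(kind)
  core <- switch(kind, plus = "CGTA", minus = "TACG", plus_cnnt = "CGTT")
  seq <- paste0(strrep("AT", 50), core, strrep("AT", 48))
  stopifnot(nchar(seq) == 200)
  sim_genome(c(chr1 = seq), seed = seed)
}

toy_site_pos0 <- function(kind = c("plus", "minus", "plus_cnnt")) {
  kind <- match.arg(kind)
  if (kind == "minus") 103L else 100L
}

# One-row methylome truth for the planted site.
toy_truth <- function(kind = c("plus", "minus", "plus_cnnt"), state = "5mC",
                      allele = 1L) {
  kind <- match.arg(kind)
  tibble::tibble(
    cell_id = 1L,
    chrom = "chr1",
    pos0 = toy_site_pos0(kind),
    strand = if (kind == "minus") "-" else "+",
    allele = allele,
    context = "CpG",
    dyad_pos0 = 100L,
    is_parental = TRUE,
    state = state
  )
}

# Small cohort used by several round-trip tests: exact capture, no duplicates.
exact_cohort <- function(n_cells = 3, e_maint = 1, h_frac = 0, seed = 5,
                         n_chrom = 2, chrom_len = 5000, snp_rate = 0.01) {
  g <- make_genome(n_chrom, chrom_len, gc = 0.5, snp_rate = snp_rate, seed = seed)
  p <- sim_params(n_cells = n_cells, e_maint = e_maint, h_frac = h_frac,
                  capture_eff = 1, dup_rate = 0, seed = seed)
  sim <- suppressMessages(simulate_cohort(g, p, read_len = 60))
  list(genome = g, params = p, sim = sim)
}

site_key <- function(cell, chrom, pos0, strand) paste(cell, chrom, pos0, strand)

# Synthetic strand-bias records (bypassing the read pipeline) for
# matrix/cluster/sister tests.
synth_records <- function(f_matrix, context = "CpG", n_total = 500L) {
  cells <- rownames(f_matrix)
  regions <- colnames(f_matrix)
  tidyr::expand_grid(cell = cells, region = regions) |>
    dplyr::mutate(
      chrom = region, start0 = NA_integer_, end0 = NA_integer_,
      allele = "all", context = context,
      f = as.vector(t(f_matrix)),
      n_total = n_total,
      n_plus = round(f * n_total), n_minus = n_total - round(f * n_total),
      pvalue = 1, significant = FALSE, masked = is.na(f)
    )
}

# Planted strand-bias matrices exercise the clustering and pairing logic
# without rerunning the read pipeline. The asymmetric population shares one
# chromosome-wise bias profile (as clonally related cells do), so the
# partition is recoverable by design.
planted_cohort <- function(n_per_group = 20, n_regions = 8, noise = 0.02, seed = 1) {
  withr::local_seed(seed)
  f_sym <- matrix(0.5, n_per_group, n_regions)
  profile <- sample(c(0.1, 0.9), n_regions, replace = TRUE)
  f_bim <- matrix(profile, n_per_group, n_regions, byrow = TRUE)
  f <- rbind(f_sym, f_bim) + matrix(stats::rnorm(2 * n_per_group * n_regions, 0, noise),
                                    2 * n_per_group, n_regions)
  f <- pmin(pmax(f, 0), 1)
  rownames(f) <- sprintf("cell%02d", seq_len(2 * n_per_group))
  colnames(f) <- paste0("chr", seq_len(n_regions))
  list(f = f, truth = rep(1:2, each = n_per_group))
}
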