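#' Assign a strand/allele-resolved methylome to one cell
#'
#' Draws cytosine states for every CpG dyad and CpA site of each haplotype
#' under a maintenance/de-novo model of DNA methylation. For each
#' (chromosome, allele) one strand is drawn as "parental" (the template
#' strand inherited through semiconservative replication); the parental-strand
#' cytosine of a CpG dyad is methylated with probability `m_parent`, and the
#' opposite ("daughter") cytosine is methylated with probability `e_maint`
#' conditional on the parental one — losing maintenance (`e_maint = 0`) leaves
#' hemi-methylated dyads on the parental strand only, which is what produces
#' chromosome-wide strand bias downstream. CpA sites are methylated
#' independently per strand with probability `d_cpa` (de novo, not copied).
#' Each methylated cytosine is converted to 5hmC with probability `h_frac`.
#'
#' Only positions whose dinucleotide is identical on both haplotypes are
#' eligible, so context and reference checks are exact on both alleles;
#' cytosines outside CpG/CpA dyad sites are implicitly unmethylated.
#'
#' @param genome A [sim_genome()].
#' @param params A [sim_params()].
#' @param cell_id Integer cell index (seeds the per-cell draws).
#' @return Tibble with one row per eligible cytosine: `cell_id`, `chrom`,
#'   `pos0`, `strand`, `allele` (1/2), `context` ("CpG"/"CpA"), `dyad_pos0`
#'   (plus-strand C of the CpG dyad, NA for CpA), `is_parental`, and
#'   `state` in {"C", "5mC", "5hmC"}.
#' @export
assign_methylome <- function(genome, params, cell_id = 1) {
  stopifnot(inherits(genome, "sim_genome"), inherits(params, "sim_params"))
  withr::local_seed(derive_seed(params$seed, 1000L + cell_id))
  haps <- haplotype_seqs(genome)
  out <- vector("list", 4L * length(genome$chromosomes))
  k <- 0L
  for (cn in names(genome$chromosomes)) {
    h1 <- haps$hap1[[cn]]
    h2 <- haps$hap2[[cn]]
    # sites shared between haplotypes (same dinucleotide on both)
    cpg <- intersect(dinuc_positions(h1, "CG"), dinuc_positions(h2, "CG"))
    cpa_plus <- intersect(dinuc_positions(h1, "CA"), dinuc_positions(h2, "CA"))
    # minus-strand CpA: minus C at p with A at its +1 <=> plus "TG" at p-1..p
    cpa_minus <- intersect(dinuc_positions(h1, "TG"), dinuc_positions(h2, "TG")) + 1L
    for (allele in 1:2) {
      parental <- sample(c("+", "-"), 1L)
      n_dyad <- length(cpg)
      if (n_dyad > 0) {
        parent_meth <- stats::runif(n_dyad) < params$m_parent
        daughter_meth <- parent_meth & (stats::runif(n_dyad) < params$e_maint)
        plus_meth <- if (parental == "+") parent_meth else daughter_meth
        minus_meth <- if (parental == "-") parent_meth else daughter_meth
        k <- k + 1L
        out[[k]] <- tibble(
          chrom = cn,
          pos0 = c(cpg, cpg + 1L),
          strand = rep(c("+", "-"), each = n_dyad),
          allele = allele,
          context = "CpG",
          dyad_pos0 = c(cpg, cpg),
          is_parental = rep(c(parental == "+", parental == "-"), each = n_dyad),
          state = if_else(c(plus_meth, minus_meth), "5mC", "C")
        )
      }
      n_cpa <- length(cpa_plus) + length(cpa_minus)
      if (n_cpa > 0) {
        k <- k + 1L
        out[[k]] <- tibble(
          chrom = cn,
          pos0 = c(cpa_plus, cpa_minus),
          strand = rep(c("+", "-"), c(length(cpa_plus), length(cpa_minus))),
          allele = allele,
          context = "CpA",
          dyad_pos0 = NA_integer_,
          is_parental = rep(c(parental == "+", parental == "-"),
                            c(length(cpa_plus), length(cpa_minus))),
          state = if_else(stats::runif(n_cpa) < params$d_cpa, "5mC", "C")
        )
      }
    }
  }
  truth <- bind_rows(out)
  if (nrow(truth) > 0 && params$h_frac > 0) {
    meth <- truth$state == "5mC"
    flip <- meth & (stats::runif(nrow(truth)) < params$h_frac)
    truth$state[flip] <- "5hmC"
  }
  truth <- mutate(truth, cell_id = as.integer(cell_id), .before = 1)
  arrange(truth, .data$chrom, .data$pos0, .data$strand, .data$allele)
}
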