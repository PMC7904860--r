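#' In silico MspJI digest of a methylome
#'
#' Emits one fragment per detectable 5mC site. MspJI recognizes mCNNR sites
#' (R = A or G three bases downstream of the methylated cytosine on its own
#' strand) and cuts 16 bp downstream of the 5mC, leaving a 4-nt 5' overhang.
#' 5hmC sites are glucosylated upstream and never cut; unmethylated cytosines
#' are not substrates. Each eligible site is captured with probability
#' `capture_eff` and tagged with a random 3-nt UMI and the cell barcode.
#'
#' @param genome A [sim_genome()].
#' @param truth Methylome tibble from [assign_methylome()].
#' @param capture_eff Per-site capture probability.
#' @param barcode 8-nt cell barcode attached to the fragments (defaults to a
#'   barcode derived from the truth's `cell_id`).
#' @param seed Integer seed for capture and UMI draws.
#' @return Tibble of fragments: `cell_id`, `barcode`, `chrom`, `allele`,
#'   `mC_pos0`, `mC_strand`, `context`, `cut_pos0`, `overhang_len` (always 4),
#'   `umi`. The cut is always exactly 16 bp downstream of the 5mC on its own
#'   strand.
#' @export
digest_mspji <- function(genome, truth, capture_eff = 1, barcode = NULL, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"))
  assert_prob(capture_eff, "capture_eff")
  cell_id <- if (nrow(truth) > 0) truth$cell_id[1] else 1L
  if (is.null(barcode)) barcode <- default_barcodes(max(cell_id, 1L))[cell_id]
  withr::local_seed(derive_seed(seed, 2000L + cell_id))
  haps <- haplotype_seqs(genome)
  sites <- filter(truth, .data$state == "5mC")
  if (nrow(sites) == 0L) {
    return(tibble(cell_id = integer(), barcode = character(), chrom = character(),
                  allele = integer(), mC_pos0 = integer(), mC_strand = character(),
                  context = character(), cut_pos0 = integer(),
                  overhang_len = integer(), umi = character()))
  }
  seqs <- c(haps$hap1, haps$hap2)
  hap_key <- paste0(sites$chrom, "|", sites$allele)
  names(seqs) <- c(paste0(names(haps$hap1), "|1"), paste0(names(haps$hap2), "|2"))
  len <- unname(nchar(genome$chromosomes)[sites$chrom])
  plus <- sites$strand == "+"
  # recognition base at +3 on the 5mC strand
  rec_pos <- if_else(plus, sites$pos0 + 3L, sites$pos0 - 3L)
  in_rec <- rec_pos >= 0L & rec_pos < len
  rec_base <- rep(NA_character_, nrow(sites))
  rec_base[in_rec] <- substring(seqs[hap_key[in_rec]], rec_pos[in_rec] + 1L,
                                rec_pos[in_rec] + 1L)
  is_R <- in_rec & if_else(plus, rec_base %in% c("A", "G"), rec_base %in% c("T", "C"))
  cut_pos0 <- if_else(plus, sites$pos0 + 16L, sites$pos0 - 16L)
  in_cut <- cut_pos0 >= 0L & cut_pos0 < len
  keep <- is_R & in_cut
  keep[is.na(keep)] <- FALSE
  if (capture_eff < 1) keep <- keep & (stats::runif(nrow(sites)) < capture_eff)
  frag <- sites[keep, c("cell_id", "chrom", "allele", "pos0", "strand", "context")]
  names(frag)[names(frag) == "pos0"] <- "mC_pos0"
  names(frag)[names(frag) == "strand"] <- "mC_strand"
  nf <- nrow(frag)
  b <- c("A", "C", "G", "T")
  frag$barcode <- rep(barcode, nf)
  frag$cut_pos0 <- cut_pos0[keep]
  frag$overhang_len <- rep(4L, nf)
  frag$umi <- paste0(sample(b, nf, replace = TRUE),
                     sample(b, nf, replace = TRUE),
                     sample(b, nf, replace = TRUE))
  select(frag, "cell_id", "barcode", "chrom", "allele", "mC_pos0",
         "mC_strand", "context", "cut_pos0", "overhang_len", "umi")
}
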