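#' Emit barcoded reads and truth alignments from digest fragments
#'
#' Builds the sequencing library: each fragment yields a read whose layout is
#' `[UMI 3 nt][cell barcode 8 nt][genomic]`. The genomic portion starts at the
#' cut coordinate and proceeds back toward (and past) the methylated cytosine,
#' so the read maps antisense to the 5mC-bearing strand with its 5' genomic
#' end at the cut. Each molecule is emitted `1 + Poisson(dup_rate)` times with
#' an identical UMI, emulating PCR/IVT duplication. A truth SAM-style
#' alignment record is produced for every read (sequence stored in
#' reference-forward orientation, as in SAM), bypassing an external aligner.
#'
#' @param fragments Tibble from [digest_mspji()].
#' @param genome A [sim_genome()].
#' @param read_len Total read length including the 11-nt UMI+barcode prefix
#'   (>= 31 so the genomic portion spans the cut-to-5mC distance).
#' @param dup_rate Mean extra duplicates per molecule.
#' @param seed Integer seed.
#' @param fastq,sam Optional output paths; written with [write_fastq()] /
#'   [write_sam()].
#' @return List with `reads` (tibble: `read_id`, `seq`, `qual`, `cell_id`,
#'   `barcode`, `umi`), `alignments` (tibble: `qname`, `flag`, `rname`, `pos`
#'   1-based, `mapq`, `cigar`, `seq`, `cell`, `umi`, `allele`), `kept`
#'   (logical vector over the input fragments), and `n_dropped` (fragments
#'   whose read would run off the chromosome end).
#' @export
emit_reads <- function(fragments, genome, read_len = 60, dup_rate = 0,
                       seed = 1, fastq = NULL, sam = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  if (read_len < 31) abort("read_len must be >= 31 (11-nt prefix + 20-nt genomic)")
  if (dup_rate < 0) abort("dup_rate must be non-negative")
  withr::local_seed(derive_seed(seed, 3000L))
  gl <- read_len - 11L
  haps <- haplotype_seqs(genome)
  seqs <- c(haps$hap1, haps$hap2)
  names(seqs) <- c(paste0(names(haps$hap1), "|1"), paste0(names(haps$hap2), "|2"))
  fr <- fragments
  len <- unname(nchar(genome$chromosomes)[fr$chrom])
  plus_mc <- fr$mC_strand == "+"
  # read antisense to the 5mC strand, 5' genomic end at the cut
  left0 <- if_else(plus_mc, fr$cut_pos0 - gl + 1L, fr$cut_pos0)
  right0 <- if_else(plus_mc, fr$cut_pos0, fr$cut_pos0 + gl - 1L)
  ok <- left0 >= 0L & right0 < len
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("emit_reads: dropped %d fragment(s) running off a chromosome end", n_dropped))
  fr <- fr[ok, ]
  left0 <- left0[ok]; right0 <- right0[ok]; plus_mc <- plus_mc[ok]
  n <- nrow(fr)
  if (n == 0L) {
    empty <- list(
      reads = tibble(read_id = character(), seq = character(), qual = character(),
                     cell_id = integer(), barcode = character(), umi = character()),
      alignments = tibble(qname = character(), flag = integer(), rname = character(),
                          pos = integer(), mapq = integer(), cigar = character(),
                          seq = character(), cell = character(), umi = character(),
                          allele = character()),
      kept = ok, n_dropped = n_dropped)
    if (!is.null(fastq)) write_fastq(empty$reads, fastq)
    if (!is.null(sam)) write_sam(empty$alignments, sam, genome)
    return(empty)
  }
  copies <- 1L + stats::rpois(n, dup_rate)
  idx <- rep.int(seq_len(n), copies)
  hap_key <- paste0(fr$chrom, "|", fr$allele)
  fwd <- unname(substring(seqs[hap_key], left0 + 1L, right0 + 1L))
  genomic <- fwd
  if (any(plus_mc)) genomic[plus_mc] <- revcomp(fwd[plus_mc])
  mol_id <- sprintf("c%d:mol%07d", fr$cell_id, seq_len(n))
  dup_no <- sequence(copies)
  read_id <- paste0(mol_id[idx], "/", dup_no)
  cell <- paste0("cell", fr$cell_id)
  reads <- tibble(
    read_id = read_id,
    seq = paste0(fr$umi[idx], fr$barcode[idx], genomic[idx]),
    qual = strrep("I", read_len),
    cell_id = fr$cell_id[idx],
    barcode = fr$barcode[idx],
    umi = fr$umi[idx]
  )
  alignments <- tibble(
    qname = read_id,
    flag = if_else(plus_mc[idx], 16L, 0L),
    rname = fr$chrom[idx],
    pos = left0[idx] + 1L,
    mapq = 60L,
    cigar = paste0(gl, "M"),
    seq = fwd[idx],
    cell = cell[idx],
    umi = fr$umi[idx],
    allele = paste0("hap", fr$allele[idx])
  )
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(sam)) write_sam(alignments, sam, genome)
  list(reads = reads, alignments = alignments, kept = ok, n_dropped = n_dropped)
}

#' Simulate a full single-cell cohort
#'
#' Runs methylome assignment, MspJI digestion, and read emission for every
#' cell of a [sim_params()] cohort on one genome, concatenating per-cell
#' outputs.
#'
#' @param genome A [sim_genome()].
#' @param params A [sim_params()].
#' @param read_len Read length passed to [emit_reads()].
#' @return List with `truth` (per-cell methylomes), `fragments`, `reads`,
#'   `alignments`, and `barcode_table` mapping barcodes to cell labels.
#' @export
simulate_cohort <- function(genome, params, read_len = 60) {
  stopifnot(inherits(genome, "sim_genome"), inherits(params, "sim_params"))
  per_cell <- purrr::map(seq_len(params$n_cells), function(i) {
    truth <- assign_methylome(genome, params, cell_id = i)
    frags <- digest_mspji(genome, truth, capture_eff = params$capture_eff,
                          barcode = params$barcodes[i],
                          seed = derive_seed(params$seed, 5000L + i))
    emitted <- emit_reads(frags, genome, read_len = read_len,
                          dup_rate = params$dup_rate,
                          seed = derive_seed(params$seed, 6000L + i))
    frags$emitted <- emitted$kept
    list(truth = truth, fragments = frags,
         reads = emitted$reads, alignments = emitted$alignments)
  })
  list(
    truth = bind_rows(purrr::map(per_cell, "truth")),
    fragments = bind_rows(purrr::map(per_cell, "fragments")),
    reads = bind_rows(purrr::map(per_cell, "reads")),
    alignments = bind_rows(purrr::map(per_cell, "alignments")),
    barcode_table = barcode_table(params$barcodes[seq_len(params$n_cells)],
                                  cell = paste0("cell", seq_len(params$n_cells)))
  )
}
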