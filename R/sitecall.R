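#' Call 5mC sites from mapped reads by cut geometry
#'
#' Inverts the MspJI cut geometry: the enzyme cuts 16 bp downstream of the
#' methylated cytosine on the 5mC strand, and library reads map antisense to
#' that strand with their 5' genomic end at the cut. A read mapped to the
#' minus strand with 5' end `p` therefore implies a candidate 5mC on the plus
#' strand at `p - offset`; a plus-strand read with 5' end `p` implies a
#' candidate on the minus strand at `p + offset`. Candidates are emitted only
#' where the reference actually carries a cytosine on the implied strand; the
#' sequence context is read from the reference base at +1 on the 5mC strand.
#'
#' @param alignments Tibble of tagged alignments (from [emit_reads()] or
#'   [read_sam()]) or a SAM path. Required columns: `qname`, `flag`, `rname`,
#'   `pos` (1-based leftmost), `cigar`, `seq`, `cell`, `umi`.
#' @param genome A [sim_genome()] or named character vector of reference
#'   sequences (haplotype 1 is used as the reference).
#' @param offset Cut-to-5mC distance in bp (default 16).
#' @return Tibble of pre-deduplication calls: `qname`, `cell`, `chrom`,
#'   `pos0`, `strand`, `context` ("CpG"/"CpA"/"CpC"/"CpT"), `allele`
#'   ("unknown" until [assign_allele()]), `umi`, `support`. QC counters
#'   (`n_reads`, `n_out_of_range`, `n_off_geometry`, `n_edge`) are attached
#'   as the `"qc"` attribute; the off-geometry count is the number of
#'   candidates whose reference base is not a cytosine.
#' @export
call_sites <- function(alignments, genome, offset = 16) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_sam(alignments)
  ref <- if (inherits(genome, "sim_genome")) genome$chromosomes else genome
  if (is.null(names(ref))) abort("reference sequences must be named")
  need <- c("qname", "flag", "rname", "pos", "cigar", "seq", "cell", "umi")
  if (!all(need %in% names(alignments)))
    abort(paste("alignments must have columns:", paste(need, collapse = ", ")))
  aln <- alignments
  gl <- unname(nchar(aln$seq))
  left0 <- aln$pos - 1L
  minus_read <- bitwAnd(aln$flag, 16L) > 0L
  five0 <- if_else(minus_read, left0 + gl - 1L, left0)
  site0 <- if_else(minus_read, five0 - as.integer(offset), five0 + as.integer(offset))
  strand <- if_else(minus_read, "+", "-")
  len <- unname(nchar(ref)[aln$rname])
  in_range <- !is.na(len) & site0 >= 0L & site0 < len
  base_at <- function(chrom, p) substring(ref[chrom], p + 1L, p + 1L)
  refbase <- rep(NA_character_, nrow(aln))
  refbase[in_range] <- base_at(aln$rname[in_range], site0[in_range])
  is_c <- in_range & if_else(strand == "+", refbase == "C", refbase == "G")
  ctx_pos <- if_else(strand == "+", site0 + 1L, site0 - 1L)
  ctx_ok <- is_c & ctx_pos >= 0L & ctx_pos < len
  ctx_base <- rep(NA_character_, nrow(aln))
  ctx_base[ctx_ok] <- base_at(aln$rname[ctx_ok], ctx_pos[ctx_ok])
  ctx_base[ctx_ok & strand == "-"] <- complement_base(ctx_base[ctx_ok & strand == "-"])
  qc <- tibble(
    n_reads = nrow(aln),
    n_out_of_range = sum(!in_range),
    n_off_geometry = sum(in_range & !is_c),
    n_edge = sum(is_c & !ctx_ok)
  )
  keep <- which(ctx_ok)
  calls <- tibble(
    qname = aln$qname[keep],
    cell = aln$cell[keep],
    chrom = aln$rname[keep],
    pos0 = site0[keep],
    strand = strand[keep],
    context = paste0("Cp", ctx_base[keep]),
    allele = "unknown",
    umi = aln$umi[keep],
    support = 1L
  )
  attr(calls, "qc") <- qc
  calls
}

#' Assign calls to parental alleles via strain SNPs
#'
#' Inspects each supporting read's bases at the SNP positions it covers:
#' reads whose covered SNP bases all match the reference are `allele1`, all
#' matching the alternate are `allele2`; conflicting evidence or no covered
#' SNP leaves the call `unknown`. SNPs whose stated reference base disagrees
#' with the reference sequence are dropped with a warning.
#'
#' @param calls Pre-deduplication calls from [call_sites()] (must retain
#'   `qname`).
#' @param alignments The alignments the calls were derived from.
#' @param snps SNP tibble (`chrom`, `pos0`, `ref`, `alt`), a [sim_genome()]
#'   (its `snps` element is used), or a VCF path.
#' @param genome Reference for SNP validation (optional when `snps` is a
#'   `sim_genome`).
#' @return `calls` with the `allele` column filled in.
#' @export
assign_allele <- function(calls, alignments, snps, genome = NULL) {
  if (inherits(snps, "sim_genome")) {
    genome <- genome %||% snps
    snps <- snps$snps
  } else if (is.character(snps) && length(snps) == 1L) {
    snps <- read_snps_vcf(snps)
  }
  snps <- as_tibble(snps)
  if (nrow(snps) == 0L) return(calls)
  if (!is.null(genome)) {
    ref <- if (inherits(genome, "sim_genome")) genome$chromosomes else genome
    obs <- substring(ref[snps$chrom], snps$pos0 + 1L, snps$pos0 + 1L)
    bad <- obs != snps$ref
    if (any(bad)) {
      warn(sprintf("dropping %d SNP(s) whose ref base disagrees with the reference", sum(bad)))
      snps <- snps[!bad, ]
    }
  }
  aln <- select(alignments, "qname", "rname", "pos", "seq")
  aln$gl <- nchar(aln$seq)
  hits <- dplyr::inner_join(aln, snps, by = c(rname = "chrom"),
                            relationship = "many-to-many")
  hits <- filter(hits, .data$pos0 >= .data$pos - 1L,
                 .data$pos0 <= .data$pos - 2L + .data$gl)
  if (nrow(hits) > 0) {
    hits$base <- substring(hits$seq, hits$pos0 - hits$pos + 2L,
                           hits$pos0 - hits$pos + 2L)
    hits$vote <- dplyr::case_when(hits$base == hits$ref ~ "allele1",
                                  hits$base == hits$alt ~ "allele2",
                                  TRUE ~ NA_character_)
    read_allele <- hits |>
      filter(!is.na(.data$vote)) |>
      group_by(.data$qname) |>
      summarise(allele = if (n_distinct(.data$vote) == 1L) .data$vote[1] else "unknown",
                .groups = "drop")
  } else {
    read_allele <- tibble(qname = character(), allele = character())
  }
  out <- calls |>
    select(-"allele") |>
    left_join(read_allele, by = "qname") |>
    mutate(allele = dplyr::coalesce(.data$allele, "unknown"))
  attr(out, "qc") <- attr(calls, "qc")
  out
}

#' Collapse PCR/IVT duplicates into unique molecule calls
#'
#' One call is kept per distinct (cell, chromosome, position, strand, UMI)
#' with `support` accumulating the collapsed read count; allele labels are
#' kept only when all supporting reads agree. Output order is deterministic.
#'
#' @param calls Calls from [call_sites()] (optionally after
#'   [assign_allele()]).
#' @return Deduplicated calls sorted by chromosome, position, strand, cell,
#'   UMI. Idempotent: `dedup(dedup(x))` equals `dedup(x)`.
#' @export
dedup <- function(calls) {
  x <- arrange(calls, .data$chrom, .data$pos0, .data$strand, .data$cell, .data$umi)
  key <- paste(x$cell, x$chrom, x$pos0, x$strand, x$umi, sep = "\r")
  first <- !duplicated(key)
  # rows with one key are adjacent after the sort, so reorder = FALSE aligns
  # the per-key aggregates with the key[first] order
  support <- as.integer(rowsum(x$support, key, reorder = FALSE)[, 1])
  has_a1 <- rowsum((x$allele == "allele1") + 0L, key, reorder = FALSE)[, 1] > 0L
  has_a2 <- rowsum((x$allele == "allele2") + 0L, key, reorder = FALSE)[, 1] > 0L
  out <- x[first, c("cell", "chrom", "pos0", "strand", "context", "allele", "umi")]
  out$support <- support
  out$allele <- dplyr::case_when(has_a1 & !has_a2 ~ "allele1",
                                 has_a2 & !has_a1 ~ "allele2",
                                 TRUE ~ "unknown")
  out <- as_tibble(out)
  attr(out, "qc") <- attr(calls, "qc")
  out
}
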