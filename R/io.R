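#' Write the two haplotype FASTA files and the SNP VCF of a genome
#'
#' @param genome A [sim_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`hap1.fa`, `hap2.fa`, `snps.vcf`).
#' @export
write_genome_fasta <- function(genome, dir) {
  stopifnot(inherits(genome, "sim_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  haps <- haplotype_seqs(genome)
  paths <- c(hap1 = file.path(dir, "hap1.fa"), hap2 = file.path(dir, "hap2.fa"),
             snps = file.path(dir, "snps.vcf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(haps$hap1), paths["hap1"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(haps$hap2), paths["hap2"])
  write_snps_vcf(genome, paths["snps"])
  invisible(paths)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write strain SNPs as a minimal VCF
#'
#' @param genome A [sim_genome()] (or tibble with `chrom`, `pos0`, `ref`,
#'   `alt`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snps_vcf <- function(genome, path) {
  snps <- if (inherits(genome, "sim_genome")) genome$snps else as_tibble(genome)
  header <- c("##fileformat=VCFv4.2",
              "##source=strandmeth",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps) > 0)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", snps$chrom, snps$pos0 + 1L,
            snps$ref, snps$alt) else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SNP VCF into the internal 0-based tibble
#'
#' Uses `vcfR` when available, otherwise a plain-text fallback for the
#' minimal VCFs written by [write_snps_vcf()].
#'
#' @param path VCF path.
#' @return Tibble `chrom`, `pos0`, `ref`, `alt`.
#' @export
read_snps_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fx) == 0)
      return(tibble(chrom = character(), pos0 = integer(),
                    ref = character(), alt = character()))
    return(tibble(chrom = fx$CHROM, pos0 = as.integer(fx$POS) - 1L,
                  ref = fx$REF, alt = fx$ALT))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(tibble(chrom = character(), pos0 = integer(),
                  ref = character(), alt = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(chrom = vapply(parts, `[`, "", 1L),
         pos0 = as.integer(vapply(parts, `[`, "", 2L)) - 1L,
         ref = vapply(parts, `[`, "", 4L),
         alt = vapply(parts, `[`, "", 5L))
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ into a read tibble
#'
#' @param path FASTQ path.
#' @return Tibble `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write alignments as a minimal tagged SAM file
#'
#' Writes the mandatory 11 columns plus `CB` (cell), `RX` (UMI) and `XA`
#' (truth haplotype) string tags. Positions are 1-based per the SAM
#' convention; sequences are stored in reference-forward orientation.
#'
#' @param alignments Alignment tibble (see [emit_reads()]).
#' @param path Output path.
#' @param genome Optional [sim_genome()] or named sequences for `@SQ` header
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, path, genome = NULL) {
  header <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(genome)) {
    ref <- if (inherits(genome, "sim_genome")) genome$chromosomes else genome
    header <- c(header,
                sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)))
  }
  a <- alignments
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tCB:Z:%s\tRX:Z:%s\tXA:Z:%s",
                  a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar, a$seq,
                  strrep("I", nchar(a$seq)), a$cell, a$umi,
                  a$allele %||% "NA")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal tagged SAM file
#'
#' @param path SAM path written by [write_sam()] (or any single-segment SAM
#'   with `CB`/`RX` string tags).
#' @return Alignment tibble `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`, `cell`, `umi`, `allele`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), cell = character(), umi = character(),
                  allele = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag_val <- function(p, tag) {
    hit <- grep(paste0("^", tag, ":Z:"), p, value = TRUE)
    if (length(hit)) sub(paste0("^", tag, ":Z:"), "", hit[1]) else NA_character_
  }
  tibble(
    qname = vapply(parts, `[`, "", 1L),
    flag = as.integer(vapply(parts, `[`, "", 2L)),
    rname = vapply(parts, `[`, "", 3L),
    pos = as.integer(vapply(parts, `[`, "", 4L)),
    mapq = as.integer(vapply(parts, `[`, "", 5L)),
    cigar = vapply(parts, `[`, "", 6L),
    seq = vapply(parts, `[`, "", 10L),
    cell = vapply(parts, tag_val, "", "CB"),
    umi = vapply(parts, tag_val, "", "RX"),
    allele = vapply(parts, tag_val, "", "XA")
  )
}

#' Write a tibble as TSV with a coordinate-convention comment header
#'
#' 0-based internal positions (`pos0`, `start0`, `end0`) are converted to
#' 1-based `pos`/`start`/`end` columns on output.
#'
#' @param x Tibble.
#' @param path Output path.
#' @param what One-line description written as a `#` comment.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(x, path, what = "strandmeth table") {
  out <- x
  if ("pos0" %in% names(out)) out <- mutate(rename(out, pos = "pos0"), pos = .data$pos + 1L)
  if ("start0" %in% names(out)) out <- mutate(rename(out, start = "start0"), start = .data$start + 1L)
  if ("end0" %in% names(out)) out <- rename(out, end = "end0")
  writeLines(sprintf("# %s; positions are 1-based, end-inclusive", what), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#'
#' Converts 1-based `pos`/`start` columns back to the internal 0-based
#' `pos0`/`start0`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_table_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if ("pos" %in% names(x)) x <- mutate(rename(x, pos0 = "pos"), pos0 = .data$pos0 - 1L)
  if ("start" %in% names(x)) x <- mutate(rename(x, start0 = "start"), start0 = .data$start0 - 1L)
  if ("end" %in% names(x)) x <- rename(x, end0 = "end")
  x
}
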