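#' Construct a diploid simulation genome
#'
#' A `sim_genome` holds a set of reference chromosome sequences plus a table
#' of strain SNPs that distinguish haplotype 1 (the reference sequence) from
#' haplotype 2 (reference with the alternate base substituted), emulating the
#' hybrid crosses used for allele-specific methylation analysis.
#'
#' @param chromosomes Named character vector of chromosome sequences
#'   (A/C/G/T only, no Ns).
#' @param snps Tibble with columns `chrom`, `pos0` (0-based), `ref`, `alt`.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `sim_genome`.
#' @export
sim_genome <- function(chromosomes, snps = NULL, seed = NA_integer_) {
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)))
    abort("chromosome sequences must be named")
  if (any(nchar(chromosomes) == 0L)) abort("chromosome sequences must be non-empty")
  if (any(grepl("[^ACGT]", chromosomes))) abort("chromosome sequences may contain only A, C, G, T")
  if (is.null(snps)) {
    snps <- tibble(chrom = character(), pos0 = integer(),
                   ref = character(), alt = character())
  }
  snps <- as_tibble(snps)
  if (nrow(snps) > 0) {
    if (any(duplicated(snps[, c("chrom", "pos0")])))
      abort("SNP positions must be unique per chromosome")
    if (any(snps$ref == snps$alt)) abort("SNP alt base must differ from ref")
    obs <- substring(chromosomes[snps$chrom], snps$pos0 + 1L, snps$pos0 + 1L)
    if (any(obs != snps$ref)) abort("SNP ref bases must match the reference sequence")
  }
  structure(list(chromosomes = chromosomes, snps = snps, seed = seed),
            class = "sim_genome")
}

#' Generate a random diploid genome with strain SNPs
#'
#' Draws i.i.d. bases at the requested GC content, then scatters biallelic
#' SNPs at rate `snp_rate` per base to create a second haplotype.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp (>= 200; shorter sequences
#'   cannot accommodate the 16-bp cut geometry plus a read). A vector of
#'   length `n_chrom` gives chromosomes of different sizes, as in a real
#'   karyotype.
#' @param gc GC content in (0, 1).
#' @param snp_rate Per-base probability of a haplotype-distinguishing SNP.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return A [sim_genome()].
#' @examples
#' g <- make_genome(n_chrom = 1, chrom_len = 1000, gc = 0.5, snp_rate = 0.01, seed = 7)
#' nchar(g$chromosomes)
#' @export
make_genome <- function(n_chrom = 1, chrom_len = 10000, gc = 0.5,
                        snp_rate = 0.001, seed = 1) {
  if (any(chrom_len < 200)) abort("chrom_len must be >= 200")
  if (gc <= 0 || gc >= 1) abort("gc must be strictly inside (0, 1)")
  assert_prob(snp_rate, "snp_rate")
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  withr::local_seed(seed)
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(base_prob), chrom_len[i], replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1))
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  snps <- purrr::map_dfr(names(chroms), function(cn) {
    pos0 <- which(stats::runif(nchar(chroms[cn])) < snp_rate) - 1L
    if (length(pos0) == 0L) return(NULL)
    ref <- substring(chroms[cn], pos0 + 1L, pos0 + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    tibble(chrom = cn, pos0 = pos0, ref = ref, alt = alt)
  })
  if (nrow(snps) == 0L) snps <- NULL
  sim_genome(chroms, snps, seed = as.integer(seed))
}

#' Haplotype sequences of a diploid genome
#'
#' @param genome A [sim_genome()].
#' @return List with named character vectors `hap1` (reference) and `hap2`
#'   (reference with SNP alternate bases substituted).
#' @export
haplotype_seqs <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  hap2 <- genome$chromosomes
  if (nrow(genome$snps) > 0) {
    for (cn in unique(genome$snps$chrom)) {
      s <- strsplit(hap2[[cn]], "", fixed = TRUE)[[1]]
      idx <- genome$snps$chrom == cn
      s[genome$snps$pos0[idx] + 1L] <- genome$snps$alt[idx]
      hap2[[cn]] <- paste(s, collapse = "")
    }
  }
  list(hap1 = genome$chromosomes, hap2 = hap2)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %s bp total, %d SNP(s), seed %s\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$snps), as.character(x$seed)))
  invisible(x)
}
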