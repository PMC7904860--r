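test_that("a minus-strand read with 5' end 26 calls a plus-strand CpG at 10", {
  ref <- c(chrA = paste0(strrep("A", 10), "CG", strrep("A", 28)))
  aln <- tibble::tibble(qname = "r1", flag = 16L, rname = "chrA", pos = 8L,
                        mapq = 60L, cigar = "20M",
                        seq = substr(ref, 8, 27), cell = "cell1", umi = "AAA")
  calls <- call_sites(aln, ref, offset = 16)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos0, 10L)   # 26 - 16
  expect_equal(calls$strand, "+")
  expect_equal(calls$context, "CpG")
})

test_that("a plus-strand read with 5' end 100 calls a minus-strand CpA at 116", {
  s <- strsplit(strrep("A", 200), "")[[1]]
  s[117] <- "G"   # minus-strand C at pos0 116
  s[116] <- "T"   # minus-strand neighbour (+1 on the minus strand) is A -> CpA
  ref <- c(chrA = paste(s, collapse = ""))
  aln <- tibble::tibble(qname = "r1", flag = 0L, rname = "chrA", pos = 101L,
                        mapq = 60L, cigar = "30M",
                        seq = substr(ref, 101, 130), cell = "cell1", umi = "AAA")
  calls <- call_sites(aln, ref, offset = 16)
  expect_equal(calls$pos0, 116L)
  expect_equal(calls$strand, "-")
  expect_equal(calls$context, "CpA")
})

test_that("candidates without a reference cytosine are counted off-geometry", {
  ref <- c(chrA = strrep("AT", 50))  # no C anywhere
  aln <- tibble::tibble(qname = "r1", flag = 16L, rname = "chrA", pos = 8L,
                        mapq = 60L, cigar = "20M", seq = strrep("A", 20),
                        cell = "cell1", umi = "AAA")
  calls <- call_sites(aln, ref)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "qc")$n_off_geometry, 1L)
  # out-of-range candidate
  aln2 <- dplyr::mutate(aln, flag = 0L, pos = 95L)  # site 110 + ... beyond 100
  calls2 <- call_sites(aln2, ref)
  expect_equal(attr(calls2, "qc")$n_out_of_range, 1L)
})

test_that("deduplication collapses identical molecules and keeps distinct UMIs", {
  base <- tibble::tibble(cell = "cell1", chrom = "chr1", pos0 = 50L, strand = "+",
                         context = "CpG", allele = "unknown", umi = "AAA",
                         support = 1L)
  three_same <- dplyr::bind_rows(base, base, base)
  d <- dedup(three_same)
  expect_equal(nrow(d), 1L)
  expect_equal(d$support, 3L)
  two_umis <- dplyr::bind_rows(base, dplyr::mutate(base, umi = "CCC"))
  expect_equal(nrow(dedup(two_umis)), 2L)
  expect_identical(dedup(dedup(three_same)), dedup(three_same))
})

test_that("deduplicated calls equal unique molecules under heavy duplication", {
  g <- make_genome(1, 4000, 0.5, 0, seed = 19)
  p <- sim_params(n_cells = 2, e_maint = 1, h_frac = 0, capture_eff = 1,
                  dup_rate = 2, seed = 19)
  sim <- suppressMessages(simulate_cohort(g, p, read_len = 60))
  calls <- dedup(call_sites(sim$alignments, g))
  fr <- dplyr::filter(sim$fragments, emitted)
  unique_molecules <- dplyr::n_distinct(
    paste(fr$cell_id, fr$chrom, fr$mC_pos0, fr$mC_strand, fr$umi))
  expect_gt(nrow(sim$reads), nrow(fr))  # duplication actually happened
  expect_equal(nrow(calls), unique_molecules)
})

test_that("round trip: called sites equal the emitted 5mC-in-mCNNR truth set", {
  co <- exact_cohort(n_cells = 3, h_frac = 0.2, seed = 23)
  calls <- dedup(call_sites(co$sim$alignments, co$genome))
  fr <- dplyr::filter(co$sim$fragments, emitted)
  expect_setequal(site_key(calls$cell, calls$chrom, calls$pos0, calls$strand),
                  site_key(paste0("cell", fr$cell_id), fr$chrom, fr$mC_pos0, fr$mC_strand))
  qc <- attr(calls, "qc")
  expect_equal(qc$n_off_geometry, 0L)
  expect_equal(qc$n_out_of_range, 0L)
  # context partition: every call in exactly one context
  expect_true(all(calls$context %in% c("CpG", "CpA", "CpC", "CpT")))
  expect_equal(sum(table(calls$context)), nrow(calls))
})

test_that("allele assignment follows SNP evidence", {
  ref <- c(chrA = paste0(strrep("A", 30), "CG", strrep("A", 68)))
  snps <- tibble::tibble(chrom = "chrA", pos0 = 40L, ref = "A", alt = "G")
  # minus reads with 5' end at pos0 46 -> call the planted C at pos0 30
  aln <- tibble::tibble(qname = c("r1", "r2"), flag = 16L, rname = "chrA",
                        pos = c(28L, 28L), mapq = 60L, cigar = "20M",
                        seq = c(paste0(substr(ref, 28, 40), "G", substr(ref, 42, 47)),
                                substr(ref, 28, 47)),
                        cell = "cell1", umi = c("AAA", "CCC"))
  calls <- call_sites(aln, ref)
  withal <- assign_allele(calls, aln, snps, ref)
  expect_equal(withal$allele[withal$qname == "r1"], "allele2")
  expect_equal(withal$allele[withal$qname == "r2"], "allele1")
  # no covered SNP -> unknown
  far <- tibble::tibble(chrom = "chrA", pos0 = 90L, ref = "A", alt = "T")
  expect_equal(unique(assign_allele(calls, aln, far, ref)$allele), "unknown")
  # disagreeing SNP table entries are dropped with a warning
  bad <- tibble::tibble(chrom = "chrA", pos0 = 40L, ref = "C", alt = "G")
  expect_warning(assign_allele(calls, aln, bad, ref), "disagrees")
})

test_that("simulated reads are allele-assigned correctly at the expected rate", {
  co <- exact_cohort(n_cells = 3, seed = 29, snp_rate = 0.01)
  calls <- assign_allele(call_sites(co$sim$alignments, co$genome),
                         co$sim$alignments, co$genome)
  truth <- dplyr::select(co$sim$alignments, qname, true = allele)
  j <- dplyr::inner_join(calls, truth, by = "qname")
  assigned <- dplyr::filter(j, allele != "unknown")
  expect_equal(mean(assigned$allele == sub("hap", "allele", assigned$true)), 1)
  # coverage expectation: a 49-nt genomic read misses all SNPs w.p. (1-rate)^49
  p_cov <- 1 - (1 - 0.01)^49
  frac <- nrow(assigned) / nrow(j)
  expect_gt(frac, p_cov - 4 * sqrt(p_cov * (1 - p_cov) / nrow(j)))
})
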