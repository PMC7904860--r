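test_that("the G-test reproduces its closed-form worked examples", {
  expect_equal(lrt_strand_bias(5, 5), 1)
  # G = 20 ln 2 = 13.862944 -> chi-squared(1) upper tail
  expect_equal(lrt_strand_bias(10, 0), 1.966377e-4, tolerance = 1e-6)
  # G = 2 (75 ln 1.5 + 25 ln 0.5) = 26.162407
  expect_equal(lrt_strand_bias(75, 25), 3.138739e-7, tolerance = 1e-6)
  # symmetry under strand swap
  expect_equal(lrt_strand_bias(30, 70), lrt_strand_bias(70, 30))
  expect_error(lrt_strand_bias(0, 0), "positive total")
  # vectorized and bounded in (0, 1]
  p <- lrt_strand_bias(0:20, 20:0)
  expect_true(all(p > 0 & p <= 1))
})

test_that("small-count records use the exact binomial p-value", {
  calls <- tibble::tibble(cell = "c", chrom = "chr1", pos0 = 0:9, strand = "+",
                          context = "CpG", allele = "unknown",
                          umi = sprintf("u%02d", 0:9), support = 1L)
  rec <- compute_bias(calls, min_sites = 1)
  expect_equal(rec$pvalue, stats::binom.test(10, 10, 0.5)$p.value)  # 2^-9
  big <- tibble::tibble(cell = "c", chrom = "chr1", pos0 = 0:29,
                        strand = rep(c("+", "-"), c(20, 10)), context = "CpG",
                        allele = "unknown", umi = sprintf("u%02d", 0:29),
                        support = 1L)
  expect_equal(compute_bias(big, min_sites = 1)$pvalue, lrt_strand_bias(20, 10))
})

test_that("strand-bias records follow the definition and conserve counts", {
  calls <- tibble::tibble(
    cell = "c", chrom = rep(c("chr1", "chr2"), c(40, 25)),
    pos0 = c(1:40, 1:25),
    strand = c(rep(c("+", "-"), c(30, 10)), rep("+", 25)),
    context = "CpG", allele = "unknown",
    umi = "AAA", support = 1L)
  rec <- compute_bias(calls, min_sites = 30)
  r1 <- rec[rec$region == "chr1", ]
  expect_equal(r1$f, 0.75)          # 30 / (30 + 10)
  expect_false(r1$masked)
  r2 <- rec[rec$region == "chr2", ]
  expect_true(r2$masked)            # 25 < min_sites, f still reported
  expect_equal(r2$f, 1)
  expect_equal(sum(rec$n_total), nrow(calls))
  expect_warning(compute_bias(calls[0, ]), "no calls")
})

test_that("binning is half-open with the last partial bin kept", {
  calls <- tibble::tibble(cell = "c", chrom = "chr1",
                          pos0 = c(0L, 9999L, 10000L, 25000L),
                          strand = "+", context = "CpG", allele = "unknown",
                          umi = c("AAA", "CCC", "GGG", "TTT"), support = 1L)
  rec <- compute_bias(calls, group = "bin", bin_size = 10000, min_sites = 1)
  expect_setequal(rec$region, c("chr1:0-10000", "chr1:10000-20000", "chr1:20000-30000"))
  expect_equal(rec$n_total[rec$region == "chr1:0-10000"], 2L)
  expect_equal(sum(rec$n_total), 4L)
})

test_that("null counts give approximately uniform LRT p-values", {
  withr::local_seed(101)
  n_bins <- 10000
  n_plus <- stats::rbinom(n_bins, 200, 0.5)
  p <- lrt_strand_bias(n_plus, 200L - n_plus)
  # exact null rejection rate of the G-test at n = 200 is 0.0560
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 4 * sqrt(0.05 * 0.95 / n_bins) + 0.006)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("plus/minus correlation hits the exact extremes", {
  mkcalls <- function(np, nm) {
    purrr::map_dfr(seq_along(np), function(i) {
      tibble::tibble(
        cell = "c", chrom = paste0("chr", i),
        pos0 = seq_len(np[i] + nm[i]),
        strand = rep(c("+", "-"), c(np[i], nm[i])),
        context = "CpG", allele = "unknown",
        umi = sprintf("u%05d", seq_len(np[i] + nm[i])), support = 1L)
    })
  }
  same <- mkcalls(c(10, 20, 40), c(10, 20, 40))
  expect_equal(plus_minus_correlation(same)$r, 1)
  mirrored <- mkcalls(c(10, 20, 40), 50 - c(10, 20, 40))
  expect_equal(plus_minus_correlation(mirrored)$r, -1)
  two <- mkcalls(c(10, 20), c(10, 20))
  res <- plus_minus_correlation(two)
  expect_true(is.na(res$r))
  expect_false(res$ok)
})

test_that("maintenance and knockout cohorts separate in plus/minus correlation", {
  lens <- c(12000, 9000, 7000, 5000, 3500)
  g <- make_genome(5, lens, 0.5, 0, seed = 41)
  run <- function(e_maint, seed) {
    p <- sim_params(n_cells = 8, e_maint = e_maint, h_frac = 0, d_cpa = 0,
                    capture_eff = 0.8, dup_rate = 0, seed = seed)
    sim <- suppressMessages(simulate_cohort(g, p, read_len = 60))
    calls <- dedup(call_sites(sim$alignments, g))
    plus_minus_correlation(calls, context = "CpG")
  }
  r_maint <- run(1, 43)$r
  r_ko <- run(0, 44)$r
  expect_gt(stats::median(r_maint), 0.8)
  expect_lt(stats::median(r_ko), 0.2)
})
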