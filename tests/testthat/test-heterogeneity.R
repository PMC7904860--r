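test_that("records spread into a complete matrix and sparse cells are dropped", {
  f <- matrix(runif(15), 3, 5,
              dimnames = list(paste0("c", 1:3), paste0("chr", 1:5)))
  mat <- build_bias_matrix(synth_records(f), min_regions = 3)
  expect_s3_class(mat, "strand_bias_matrix")
  expect_equal(dim(mat$f), c(3L, 5L))
  expect_false(any(mat$mask))
  f2 <- f
  f2[1, 2:5] <- NA  # cell c1 keeps a single unmasked region
  expect_message(mat2 <- build_bias_matrix(synth_records(f2), min_regions = 3),
                 "dropping 1 cell")
  expect_equal(rownames(mat2$f), c("c2", "c3"))
  f3 <- f; f3[] <- NA
  expect_error(suppressMessages(build_bias_matrix(synth_records(f3))), "no cells")
  long <- generics::tidy(mat)
  expect_equal(nrow(long), 15L)
  expect_equal(sort(unique(long$cell)), sort(rownames(f)))
})

test_that("silhouette model selection recovers the planted two populations", {
  pc <- planted_cohort(seed = 31)
  mat <- build_bias_matrix(synth_records(pc$f), min_regions = 3)
  cl <- cluster_cells(mat, k_range = 1:5, n_restarts = 10, seed = 3)
  expect_equal(cl$k, 2L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$labels, pc$truth), 1)
  sil <- cl$silhouette
  s2 <- sil$mean_silhouette[sil$k == 2]
  expect_true(all(s2 > sil$mean_silhouette[sil$k %in% 3:5]))
})

test_that("identical cells collapse to a single cluster", {
  f <- matrix(0.5, 8, 4, dimnames = list(paste0("c", 1:8), paste0("chr", 1:4)))
  mat <- build_bias_matrix(synth_records(f), min_regions = 3)
  cl <- cluster_cells(mat, k_range = 1:4, seed = 1)
  expect_equal(cl$k, 1L)
  expect_true(all(cl$labels == 1L))
})

test_that("clustering is deterministic for a fixed seed and errors on bad k", {
  pc <- planted_cohort(seed = 37)
  mat <- build_bias_matrix(synth_records(pc$f), min_regions = 3)
  c1 <- cluster_cells(mat, k_range = 1:4, seed = 11)
  c2 <- cluster_cells(mat, k_range = 1:4, seed = 11)
  expect_identical(c1$labels, c2$labels)
  expect_error(cluster_cells(mat, k_range = 1:100), "k_range")
})

test_that("cell bias variance matches hand-computed values", {
  f <- rbind(c(0.5, 0.5, 0.5), c(0, 1, NA), c(NA, NA, 0.3))
  dimnames(f) <- list(paste0("c", 1:3), paste0("chr", 1:3))
  mat <- suppressMessages(build_bias_matrix(synth_records(f), min_regions = 1))
  v <- cell_bias_variance(mat)
  expect_equal(v$variance[v$cell == "c1"], 0)
  expect_equal(v$variance[v$cell == "c2"], 0.5)  # var of (0, 1)
  expect_true(is.na(v$variance[v$cell == "c3"]))
})

test_that("knockout cells have far larger bias variance than maintenance cells", {
  withr::local_seed(53)
  maint <- matrix(pmin(pmax(0.5 + stats::rnorm(60, 0, 0.02), 0), 1), 10, 6)
  ko <- matrix(sample(c(0.05, 0.95), 60, replace = TRUE), 10, 6)
  f <- rbind(maint, ko)
  dimnames(f) <- list(sprintf("c%02d", 1:20), paste0("chr", 1:6))
  mat <- build_bias_matrix(synth_records(f), min_regions = 3)
  v <- cell_bias_variance(mat)
  expect_gt(min(v$variance[11:20]), 10 * max(v$variance[1:10]))
})

test_that("a planted mirrored pair is found and null cohorts yield none", {
  withr::local_seed(59)
  nr <- 12
  base <- stats::runif(nr, 0.1, 0.9)
  f <- rbind(a = base, b = 1 - base,
             matrix(pmin(pmax(0.5 + stats::rnorm(8 * nr, 0, 0.03), 0), 1), 8, nr))
  rownames(f) <- c("a", "b", sprintf("n%02d", 1:8))
  colnames(f) <- paste0("chr", seq_len(nr))
  mat <- build_bias_matrix(synth_records(f), min_regions = 3)
  pairs <- find_sisters(mat, r_threshold = -0.8)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$cell_a, pairs$cell_b), c("a", "b"))
  expect_equal(pairs$r, -1, tolerance = 1e-9)
  # null cohort: symmetric cells only, 20 regions so chance anti-correlation
  # at -0.8 is vanishingly rare
  null_f <- matrix(pmin(pmax(0.5 + stats::rnorm(400, 0, 0.03), 0), 1), 20, 20,
                   dimnames = list(sprintf("n%02d", 1:20), paste0("chr", 1:20)))
  null_mat <- build_bias_matrix(synth_records(null_f), min_regions = 3)
  expect_equal(nrow(find_sisters(null_mat, r_threshold = -0.8)), 0L)
})

test_that("sister pairing is a matching and invariant to row order", {
  withr::local_seed(61)
  nr <- 12
  b1 <- stats::runif(nr, 0.1, 0.9); b2 <- stats::runif(nr, 0.1, 0.9)
  f <- rbind(a1 = b1, a2 = 1 - b1, b1 = b2, b2 = 1 - b2)
  colnames(f) <- paste0("chr", seq_len(nr))
  mat <- build_bias_matrix(synth_records(f), min_regions = 3)
  pairs <- find_sisters(mat, r_threshold = -0.8)
  expect_equal(nrow(pairs), 2L)
  expect_equal(anyDuplicated(c(pairs$cell_a, pairs$cell_b)), 0L)
  perm <- f[sample(nrow(f)), ]
  mat_p <- build_bias_matrix(synth_records(perm), min_regions = 3)
  pairs_p <- find_sisters(mat_p, r_threshold = -0.8)
  norm <- function(p) {
    key <- purrr::map2_chr(p$cell_a, p$cell_b, ~ paste(sort(c(.x, .y)), collapse = "+"))
    sort(key)
  }
  expect_equal(norm(pairs), norm(pairs_p))
})

test_that("simulated post-division sisters are recovered from reads", {
  # two 2-cell embryos: within an embryo the daughters inherit complementary
  # template strands, so the sister of a simulated cell carries the mirrored
  # per-chromosome bias profile (f -> 1 - f)
  g <- make_genome(8, 6000, 0.5, 0, seed = 67)
  p <- sim_params(n_cells = 2, e_maint = 0, h_frac = 0, d_cpa = 0,
                  capture_eff = 1, dup_rate = 0, seed = 67)
  sim1 <- suppressMessages(simulate_cohort(g, p, read_len = 60))
  calls <- dedup(call_sites(sim1$alignments, g))
  rec <- compute_bias(calls, context = "CpG", min_sites = 20)
  sister_rec <- rec |>
    dplyr::mutate(cell = sub("cell1", "cell1s", sub("cell2", "cell2s", cell)),
                  f = 1 - f,
                  n_plus2 = n_minus, n_minus = n_plus, n_plus = n_plus2) |>
    dplyr::select(-n_plus2)
  mat <- build_bias_matrix(dplyr::bind_rows(rec, sister_rec),
                           min_regions = 3, split_allele = TRUE)
  pairs <- find_sisters(mat, r_threshold = -0.8)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(purrr::map2_chr(pairs$cell_a, pairs$cell_b,
                                  ~ paste(sort(c(.x, .y)), collapse = "+")),
                  c("cell1+cell1s", "cell2+cell2s"))
})
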