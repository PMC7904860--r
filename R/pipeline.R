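pipeline_defaults <- function() {
  list(
    outdir = "strandmeth_out",
    seed = 1L,
    genome = list(n_chrom = 3L, chrom_len = 20000L, gc = 0.5, snp_rate = 0.001),
    params = list(m_parent = 0.8, e_maint = 0.95, d_cpa = 0.02, h_frac = 0.05,
                  capture_eff = 0.3, dup_rate = 0.5, conv_err = 0.005,
                  n_cells = 12L),
    read_len = 60L,
    reference = NULL,
    max_mismatch = 0L,
    offset = 16L,
    bias = list(group = "chromosome", bin_size = NULL, context = "CpG",
                allele = NULL, min_sites = 50L, alpha = 0.05),
    cluster = list(k_range = 1:4, n_restarts = 10L, min_regions = 3L,
                   split_allele = FALSE),
    sisters = list(r_threshold = -0.8, min_shared = 3L),
    hairpin = list(n_dyads = 20000L)
  )
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    abort(sprintf("unknown %s key(s): %s", path, paste(bad, collapse = ", ")))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, "$", k))
    else user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration, rejects unknown keys, and fills in defaults.
#'
#' @param path YAML path, or a named list of overrides.
#' @return Resolved configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL
          else if (is.character(path)) yaml::read_yaml(path)
          else path
  cfg <- merge_config(pipeline_defaults(), user)
  structure(cfg, class = "pipeline_config")
}

#' Run the simulate-to-sisters pipeline
#'
#' Executes the stages in order — simulate, demultiplex, call (geometry,
#' allele assignment, deduplication), strand bias, correlations, clustering,
#' sister detection, hairpin — writing every stage's table beside a manifest
#' of output MD5 hashes and the resolved configuration. Reruns with the same
#' configuration and seed reproduce the hashes.
#'
#' @param config A [read_pipeline_config()] result, a YAML path, or a named
#'   list of overrides.
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, a list with the `manifest` tibble (stage, file, md5)
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(cfg$reference) && !file.exists(cfg$reference))
    abort(sprintf("reference path does not exist: %s", cfg$reference))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); stages <- character(0)
  emit <- function(stage, name, writer) {
    path <- file.path(cfg$outdir, name)
    writer(path)
    files <<- c(files, path); stages <<- c(stages, stage)
    path
  }

  # simulate
  genome <- make_genome(cfg$genome$n_chrom, cfg$genome$chrom_len, cfg$genome$gc,
                        cfg$genome$snp_rate, seed = cfg$seed)
  params <- do.call(sim_params, c(cfg$params, list(seed = cfg$seed)))
  sim <- simulate_cohort(genome, params, read_len = cfg$read_len)
  emit("simulate", "hap1.fa", function(p) write_genome_fasta(genome, cfg$outdir))
  files <- c(files, file.path(cfg$outdir, c("hap2.fa", "snps.vcf")))
  stages <- c(stages, "simulate", "simulate")
  emit("simulate", "reads.fastq", function(p) write_fastq(sim$reads, p))
  emit("simulate", "truth.sam", function(p) write_sam(sim$alignments, p, genome))
  emit("simulate", "truth_methylome.tsv",
       function(p) write_table_tsv(sim$truth, p, "simulated methylome truth"))

  # demultiplex (validates barcodes on the FASTQ reads)
  dm <- demultiplex(sim$reads, sim$barcode_table, max_mismatch = cfg$max_mismatch)
  emit("demux", "demux_report.tsv",
       function(p) write_table_tsv(dm$per_cell, p, "reads per cell after demultiplexing"))

  # call
  calls_raw <- call_sites(sim$alignments, genome, offset = cfg$offset)
  calls_raw <- assign_allele(calls_raw, sim$alignments, genome)
  calls <- dedup(calls_raw)
  emit("call", "calls.tsv",
       function(p) write_table_tsv(calls, p, "deduplicated 5mC calls"))
  emit("call", "call_qc.tsv",
       function(p) write_table_tsv(attr(calls_raw, "qc"), p, "site-calling QC counters"))

  # strand bias
  records <- compute_bias(calls, group = cfg$bias$group, bin_size = cfg$bias$bin_size,
                          context = cfg$bias$context, allele = cfg$bias$allele,
                          min_sites = cfg$bias$min_sites, alpha = cfg$bias$alpha)
  emit("bias", "strand_bias.tsv",
       function(p) write_table_tsv(records, p, "strand-bias records"))
  correlations <- plus_minus_correlation(calls, group = cfg$bias$group,
                                         bin_size = cfg$bias$bin_size,
                                         context = cfg$bias$context)
  emit("bias", "plus_minus_correlation.tsv",
       function(p) write_table_tsv(correlations, p, "per-cell plus/minus correlations"))

  # cluster + sisters (pooled-allele records to keep one record per region)
  rec_mat <- compute_bias(calls, group = cfg$bias$group, bin_size = cfg$bias$bin_size,
                          context = cfg$bias$context, min_sites = cfg$bias$min_sites)
  mat <- build_bias_matrix(rec_mat, min_regions = cfg$cluster$min_regions,
                           split_allele = TRUE)
  clus <- cluster_cells(mat, k_range = cfg$cluster$k_range,
                        n_restarts = cfg$cluster$n_restarts, seed = cfg$seed)
  emit("cluster", "clusters.tsv",
       function(p) write_table_tsv(generics::tidy(clus), p, "cell cluster labels"))
  emit("cluster", "silhouette.tsv",
       function(p) write_table_tsv(clus$silhouette, p, "mean silhouette per candidate k"))
  sis <- find_sisters(mat, r_threshold = cfg$sisters$r_threshold,
                      min_shared = cfg$sisters$min_shared)
  emit("sisters", "sister_pairs.tsv",
       function(p) write_table_tsv(sis, p, "anti-correlated sister-cell pairs"))

  # hairpin
  hp <- simulate_hairpin(cfg$hairpin$n_dyads, m_parent = params$m_parent,
                         e_maint = params$e_maint, conv_err = params$conv_err,
                         seed = cfg$seed)
  dy <- classify_dyads(hp)
  corr <- correct_conversion(dy, conv_err = params$conv_err, seed = cfg$seed)
  emit("hairpin", "dyad_summary.tsv",
       function(p) write_table_tsv(dplyr::bind_cols(dy, select(corr, -"conv_err")),
                                   p, "CpG dyad summary and corrected maintenance"))

  cfg_path <- file.path(cfg$outdir, "config_resolved.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- tibble(stage = stages, file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  write_table_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"),
                  "pipeline output manifest")
  invisible(list(manifest = manifest, genome = genome, params = params,
                 calls = calls, records = records, correlations = correlations,
                 matrix = mat, clusters = clus, sisters = sis,
                 dyads = dplyr::bind_cols(dy, select(corr, -"conv_err"))))
}
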