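# Demo configuration for `strandmeth run` / run_pipeline(): a small diploid
# genome and a 12-cell cohort that finishes in well under a minute.
outdir: strandmeth_demo
seed: 42
genome:
  n_chrom: 3
  chrom_len: 12000
  gc: 0.5
  snp_rate: 0.002
params:
  m_parent: 0.8
  e_maint: 0.95
  d_cpa: 0.02
  h_frac: 0.05
  capture_eff: 0.5
  dup_rate: 0.5
  conv_err: 0.005
  n_cells: 12
read_len: 60
bias:
  group: chromosome
  context: CpG
  min_sites: 30
cluster:
  k_range: [1, 2, 3, 4]
  min_regions: 2
sisters:
  r_threshold: -0.8
  min_shared: 3
hairpin:
  n_dyads: 20000
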