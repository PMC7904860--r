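---
title: "Strand-specific single-cell 5mC: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific single-cell 5mC: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandmeth)
library(dplyr)
```

## The problem

After DNA replication, the maintenance methyltransferase DNMT1 copies CpG
methylation from the template strand onto the newly synthesized strand. When
maintenance is intact, every methylated CpG dyad is symmetric and the two
strands of a chromosome carry equal amounts of 5mC. When maintenance fails,
new strands stay unmethylated, dyads become hemi-methylated, and — because
replication is semiconservative — whole chromosomes become strand-biased:
nearly all 5mC sits on one strand. Measuring, per cell and per chromosome,
the *strand bias*

$$ f = \frac{n_+}{n_+ + n_-} $$

(the fraction of detected 5mCpG sites on the plus strand) therefore separates
*passive* demethylation (loss of maintenance, $f$ near 0 or 1) from *active*
demethylation (5mC oxidized to 5hmC and removed; strands stay symmetric,
$f \approx 0.5$, while total 5mC falls).

strandmeth implements the computational side of a single-cell assay built on
the methylation-dependent restriction enzyme MspJI: 5hmC is first hidden by
glucosylation, MspJI then recognizes methylated cytosines in the
\(^{m}\)CNNR context (R = A/G three bases downstream on the 5mC strand) and
cuts 16 bp downstream of the 5mC, leaving a 4-nt 5′ overhang to which a
barcoded adapter is ligated. The read layout is
`[UMI 3 nt][cell barcode 8 nt][genomic]`, and the genomic portion maps
antisense to the 5mC strand with its 5′ end at the cut. Inverting that
geometry recovers the methylated cytosine exactly 16 bp away.

## The simulator and what it emulates

Every downstream stage is tested against a generative model
(`make_genome()`, `sim_params()`, `assign_methylome()`, `digest_mspji()`,
`emit_reads()`, `simulate_cohort()`), so the whole pipeline is verifiable
without any sequencing data.

* **Genome.** I.i.d. bases at a chosen GC content, with biallelic strain SNPs
  scattered at `snp_rate` per base to emulate a hybrid cross (two
  haplotypes). Chromosomes may differ in length, as in a real karyotype;
  this matters because per-cell plus/minus count correlations are driven by
  region-size variation.
* **Methylome.** Per (chromosome, allele, cell) one strand is drawn as
  parental. Each CpG dyad is methylated on the parental strand with
  probability `m_parent`; the daughter strand copies it with probability
  `e_maint` — the DNMT1 axis. CpA sites are methylated independently per
  strand with probability `d_cpa` (de novo, never copied), and any
  methylated site is 5hmC instead of 5mC with probability `h_frac`.
  Sites whose dinucleotide differs between haplotypes (a SNP hitting the C
  or its +1 base) are left unmethylated on both alleles, so context
  classification and reference validation stay exact for every allele.
  States are stored for all CpG-dyad and CpA cytosines; other cytosines are
  implicitly unmethylated because the model never methylates them.
* **Digest and library.** A fragment is emitted per 5mC in
  \(^{m}\)CNNR context with probability `capture_eff`; 5hmC and unmethylated
  cytosines are never cut. Each molecule receives a random 3-nt UMI and is
  read `1 + Poisson(dup_rate)` times; duplicates share UMI and position
  exactly. The truth SAM bypasses an external aligner (alignment is out of
  scope), and there are no sequencing errors in the genomic portion — the
  simulator isolates the pipeline logic it is meant to test.

Default parameters describe a maintenance-competent somatic cell:
`m_parent = 0.8` (typical bulk CpG methylation), `e_maint = 0.95` (high but
imperfect maintenance fidelity), `d_cpa = 0.02` (non-CpG methylation is
rare), `h_frac = 0.05`, `capture_eff = 0.3`, `dup_rate = 0.5`, and
`conv_err = 0.005` (bisulfite conversion failure below 1%). These are the
simulation's study conditions; scenario scripts override `e_maint` (1 for
the maintenance null, 0 for the knockout regime) rather than the defaults.

What the simulator does **not** emulate — and hence what green tests do not
show about real data: sequencing and mapping errors, enzyme-kinetic biases
(double-site requirements, fragment-size selection), amplification bias
beyond duplicate counts, and real genomic base composition (CpG islands,
repeats). Real libraries will have off-geometry reads; the caller counts and
reports them instead of assuming they are absent.

## From reads to calls

`demultiplex()` assigns a read iff exactly one barcode matches positions
4–11 within `max_mismatch` Hamming errors (default 0 — only the correct
barcode is accepted; 1 is available behind the flag). The 3-nt UMI is kept
verbatim: with only 64 possible UMIs, error correction would merge distinct
molecules far more often than it would fix errors. `call_sites()` inverts
the cut geometry at a fixed `offset = 16` (the dominant cut distance; no
±window by default, favouring precision), validates that the reference
carries a C on the implied strand, classifies the context from the +1 base,
and reports off-geometry and out-of-range counters. `assign_allele()` uses
only SNP bases inside the supporting read and returns `unknown` on conflict
rather than majority-voting, again because of the tiny UMI space.
`dedup()` collapses reads per (cell, position, strand, UMI), so two alleles
caught at one site are kept apart exactly when their UMIs differ.

## The strand-bias test

For counts $(n_+, n_-)$ the departure from the symmetric null $p = 0.5$ is
tested with the binomial likelihood-ratio (G) statistic

$$ G = 2\left[n_+\ln\frac{\hat f}{0.5} + n_-\ln\frac{1-\hat f}{0.5}\right],
\qquad \hat f = \frac{n_+}{n_+ + n_-}, $$

referred to $\chi^2_1$ (`lrt_strand_bias()`). Zero-count terms contribute 0,
and the p-value is symmetric under strand swap. In `compute_bias()` records
with fewer than 25 sites use the exact binomial test instead, because the
asymptotics are poor there; records below `min_sites = 50` are masked — kept
with their $f$, flagged, and excluded from statistics — so matrices retain
their shape. No multiple-testing correction is applied by default (the
`significant` flag is raw $P < 0.05$); adjust `pvalue` downstream if needed.
Note the G-test's exact size at $n = 200$ is 0.056, not 0.050 — binomial
discreteness, visible in the calibration checks.

```{r lrt}
lrt_strand_bias(c(5, 10, 75), c(5, 0, 25))
```

## Heterogeneity, clustering, sisters

`build_bias_matrix()` spreads records into a cells × regions matrix of $f$
with a missingness mask. For k-means and silhouette computation only, masked
entries are imputed with 0.5 — the maintenance expectation, a neutral value
that pulls no cell toward the asymmetric extremes; mask-aware distances add
complexity without benefit at these matrix sizes. `cluster_cells()` picks
the k (best of `n_restarts` k-means runs per candidate) that maximizes the
mean silhouette width; when no $k \ge 2$ has a defined silhouette (all cells
identical), one cluster is reported. A planted-partition caveat: a
population whose per-chromosome biases are independent draws in
$\{0.1, 0.9\}$ occupies $2^{\#regions}$ hypercube corners and is not one
k-means cluster; recovery tests therefore plant a *shared* bias profile for
the asymmetric group, which is also the biologically coherent case (clonally
related cells inherit correlated template strands).

`find_sisters()` exploits the mirror symmetry of daughters of one division:
unreplicated strand marks make their chromosome-wise $f$ vectors
anti-correlated. A pair is reported iff its Pearson r over at least
`min_shared = 3` shared unmasked regions is at most `r_threshold = -0.8`
*and* the two cells are mutually each other's most-negative partner;
remaining conflicts resolve greedily by ascending r, so the result is a
matching. The thresholds are this package's defaults (declared, not
inferred): −0.8 demands that anti-correlation span essentially all
chromosomes, and with ≥ 12 informative regions the chance of a spurious
−0.8 among symmetric cells is negligible, which the null-cohort tests
confirm.

## Hairpin-bisulfite dyad analysis

Hairpin libraries covalently link the two strands of a fragment, so one read
pair reports both cytosines of each CpG dyad. `classify_dyads()` counts
symmetric, hemi-methylated, and unmethylated dyads;
`frac_symmetric_of_methylated` = sym/(sym+hemi) is the direct maintenance
read-out (under the model its expectation is `e_maint`), and
`frac_symmetric_of_all` is also emitted since either denominator may be
wanted. Bisulfite read-out flips each strand's state with probability
`conv_err`; `correct_conversion()` inverts the induced 3×3 class confusion
by method of moments (exact identity at `conv_err = 0`), clips to [0, 1]
with a warning if the inversion leaves the simplex, and attaches a seeded
multinomial-bootstrap percentile CI.

```{r hairpin}
hp <- simulate_hairpin(50000, m_parent = 0.8, e_maint = 0.7,
                       conv_err = 0.02, seed = 1)
correct_conversion(classify_dyads(hp), conv_err = 0.02, seed = 1)
```

## Numerical and interface conventions

* Coordinates are 0-based half-open internally; every TSV writes 1-based
  positions and says so in its header comment. Binning is 0-based half-open
  with the last partial bin kept.
* All stochastic stages take explicit integer seeds; per-cell and per-stage
  streams are derived deterministically from the base seed, and identical
  seeds reproduce outputs byte-for-byte (the pipeline manifest records MD5
  hashes to prove it).
* Degenerate inputs are flagged, not silently dropped: zero-count records
  are masked with `f = NA`; correlations need ≥ 3 usable regions; dyad
  summaries without methylated dyads return `NA` with a warning.
* Problem sizes in the bundled checks are desk-scale by design — a few
  chromosomes of tens of kilobases and cohorts of 2–50 cells — chosen so
  each property is measured with comfortable Monte-Carlo margins (counts of
  thousands of dyads per chromosome where a ±0.02 claim is made).

## Known limitations

Alignment, bisulfite-space calling, 5hmC subtraction (which requires a
companion hydroxymethylation assay), enrichment profiles over genomic
elements, and embedding plots (t-SNE/UMAP) are out of scope; clusters come
from k-means labels, not from an embedding. The simulator treats each
recognition site independently and models the 4-nt overhang as an annotation
only. Sister detection assumes chromosome-scale coherence of strand bias;
sub-chromosomal recombination of patterns would weaken it.
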