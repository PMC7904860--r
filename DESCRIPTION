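Package: strandmeth
Title: Strand-Specific Single-Cell DNA Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strand-specific, allele-aware quantification of
    5-methylcytosine in single cells from methylation-dependent
    restriction-enzyme (MspJI) digestion libraries. Includes a diploid
    read simulator with ground truth, cell-barcode/UMI demultiplexing,
    cut-geometry 5mC site calling with PCR deduplication and SNP-based
    allele assignment, binomial likelihood-ratio strand-bias tests,
    cell-heterogeneity clustering with silhouette model selection,
    sister-cell detection by chromosome-wise anti-correlation, and
    hairpin-bisulfite CpG-dyad maintenance estimation with
    conversion-error correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
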