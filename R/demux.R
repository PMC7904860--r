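#' Build and validate a cell barcode table
#'
#' @param barcode Character vector of equal-width cell barcodes.
#' @param cell Optional cell labels (defaults to `cell1`, `cell2`, ...).
#' @return Tibble with columns `barcode`, `cell`. Warns if any pair of
#'   barcodes is closer than Hamming distance 2 (a single error could then
#'   switch cells).
#' @export
barcode_table <- function(barcode, cell = NULL) {
  if (length(barcode) == 0L) abort("barcode table must be non-empty")
  if (length(unique(nchar(barcode))) != 1L) abort("all barcodes must have equal width")
  if (anyDuplicated(barcode)) abort("barcodes must be unique")
  if (is.null(cell)) cell <- paste0("cell", seq_along(barcode))
  if (length(cell) != length(barcode)) abort("`cell` must match `barcode` in length")
  if (length(barcode) > 1L) {
    d <- hamming_matrix(barcode, barcode)
    diag(d) <- NA_integer_
    if (min(d, na.rm = TRUE) < 2L)
      warn("some barcodes are within Hamming distance 1 of each other")
  }
  tibble(barcode = barcode, cell = cell)
}

#' Demultiplex reads by cell barcode
#'
#' Reads carry the layout `[UMI 3 nt][barcode 8 nt][genomic]`. A read is
#' assigned to a cell iff exactly one barcode in the table matches its
#' positions 4-11 within `max_mismatch` Hamming errors; reads matching no
#' barcode, matching several equally acceptably, or shorter than 12 nt are
#' left unassigned with a reason. The UMI (positions 1-3) is kept verbatim
#' and never error-corrected.
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual` (e.g. from
#'   [emit_reads()] or [read_fastq()]), or a FASTQ path.
#' @param barcodes A [barcode_table()] (or character vector of barcodes).
#' @param max_mismatch Maximum Hamming mismatches tolerated in the barcode
#'   (0 or 1; default 0).
#' @return List with `reads` (tibble `read_id`, `cell`, `umi`, `seq` trimmed
#'   to the genomic portion, `qual`), `per_cell` counts, `unassigned` tibble
#'   of reasons, and counts `n_total`, `n_assigned`, `n_unassigned`
#'   (conserving `n_total = n_assigned + n_unassigned`).
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 0) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (!is.data.frame(barcodes)) barcodes <- barcode_table(barcodes)
  if (!max_mismatch %in% c(0L, 1L)) abort("max_mismatch must be 0 or 1")
  if (!all(c("read_id", "seq") %in% names(reads)))
    abort("`reads` must have columns read_id and seq")
  if (any(c("cell", "umi") %in% names(reads)) && !"barcode" %in% names(reads))
    abort("reads appear to be demultiplexed already")
  bw <- nchar(barcodes$barcode[1])
  n_total <- nrow(reads)
  lens <- nchar(reads$seq)
  long_enough <- lens >= 3L + bw + 1L
  bc_obs <- substr(reads$seq, 4L, 3L + bw)
  assigned_cell <- rep(NA_character_, n_total)
  reason <- rep(NA_character_, n_total)
  reason[!long_enough] <- "too_short"
  exact <- match(bc_obs, barcodes$barcode)
  if (max_mismatch == 0L) {
    hit <- long_enough & !is.na(exact)
    assigned_cell[hit] <- barcodes$cell[exact[hit]]
    reason[long_enough & is.na(exact)] <- "no_match"
  } else {
    u <- unique(bc_obs[long_enough])
    d <- hamming_matrix(u, barcodes$barcode)
    n_within <- rowSums(d <= max_mismatch)
    best <- apply(d, 1L, which.min)
    u_cell <- if_else(n_within == 1L, barcodes$cell[best], NA_character_)
    u_reason <- dplyr::case_when(n_within == 0L ~ "no_match",
                                 n_within > 1L ~ "ambiguous",
                                 TRUE ~ NA_character_)
    m <- match(bc_obs, u)
    assigned_cell[long_enough] <- u_cell[m[long_enough]]
    reason[long_enough] <- u_reason[m[long_enough]]
  }
  hit <- !is.na(assigned_cell)
  tagged <- tibble(
    read_id = reads$read_id[hit],
    cell = assigned_cell[hit],
    umi = substr(reads$seq[hit], 1L, 3L),
    seq = substr(reads$seq[hit], 3L + bw + 1L, lens[hit]),
    qual = if ("qual" %in% names(reads))
      substr(reads$qual[hit], 3L + bw + 1L, lens[hit]) else NA_character_
  )
  per_cell <- tagged |>
    dplyr::count(.data$cell, name = "n_reads") |>
    tidyr::complete(cell = barcodes$cell, fill = list(n_reads = 0L)) |>
    arrange(.data$cell)
  unassigned <- tibble(read_id = reads$read_id[!hit], reason = reason[!hit])
  stopifnot(nrow(tagged) + nrow(unassigned) == n_total)
  list(reads = tagged, per_cell = per_cell, unassigned = unassigned,
       n_total = n_total, n_assigned = nrow(tagged),
       n_unassigned = nrow(unassigned))
}
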