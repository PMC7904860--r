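#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join n n_distinct bind_rows across all_of if_else row_number rename
#' @keywords internal
"_PACKAGE"

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distances between each string in `x` and each string in `table`.
# All strings must share one width. Returns a length(x) x length(table) matrix.
hamming_matrix <- function(x, table) {
  w <- unique(nchar(c(x, table)))
  if (length(w) != 1L) abort("all sequences must have equal width for Hamming comparison")
  mx <- matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = w, byrow = TRUE)
  out <- matrix(0L, nrow = length(x), ncol = length(table))
  for (j in seq_along(table)) {
    bj <- strsplit(table[j], "", fixed = TRUE)[[1]]
    out[, j] <- as.integer(rowSums(mx != matrix(bj, nrow = length(x), ncol = w, byrow = TRUE)))
  }
  out
}

# Deterministic per-stream seed derived from a base seed; kept inside 32-bit range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483587) + 1L
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  invisible(x)
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

# Start positions (0-based) of a fixed dinucleotide in a sequence string.
dinuc_positions <- function(seq, dinuc) {
  hits <- gregexpr(dinuc, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}
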