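# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Random open reading frame: ATG + non-stop codons + TAA.
#' @noRd
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  codons <- character(n_codons)
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  body <- replicate(n_codons - 2L, {
    repeat {
      cod <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!(cod %in% STOP_CODONS)) return(cod)
    }
  })
  codons[2:(n_codons - 1L)] <- body
  paste(codons, collapse = "")
}

#' @noRd
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
chars_to_seq <- function(x) paste(x, collapse = "")

# Codon strings of a nucleotide sequence, truncated to complete codons.
#' @noRd
codons_of <- function(seq) {
  n <- floor(nchar(seq) / 3L)
  if (n == 0L) return(character(0))
  starts <- (seq_len(n) - 1L) * 3L + 1L
  substring(seq, starts, starts + 2L)
}

# Merge 1-based inclusive intervals (two-column matrix/data.frame start,end);
# overlapping or book-ended intervals are fused.
#' @noRd
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# Total overlap (bp) between one interval set and another, both 1-based
# inclusive data.frames with columns start/end.
#' @noRd
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ia <- IRanges::IRanges(start = a$start, end = a$end)
  ib <- IRanges::IRanges(start = b$start, end = b$end)
  ov <- IRanges::intersect(ia, IRanges::reduce(ib))
  sum(IRanges::width(ov))
}

# Stage seeds derived from one master seed; kept well below .Machine$integer.max.
#' @noRd
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
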