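# Small sequence utilities shared across modules. All sequence handling is on
# plain uppercase character vectors; Biostrings is used at the file boundary.

IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Normalize nucleotide sequences
#'
#' Uppercases and maps RNA `U` to `T`. Other IUPAC codes pass through.
#'
#' @param x character vector of sequences.
#' @return normalized character vector.
#' @export
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Reverse complement
#'
#' @param x character vector of IUPAC DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Position-wise (non-reversed) complement; used e.g. for the klMA identifier,
# which is the complement of the IgG1 identifier in read orientation.
complement_seq <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", normalize_seq(x))
}

#' Hamming distance between equal-length sequences
#'
#' `N` (or any differing character) counts as a mismatch.
#'
#' @param a,b character scalars of equal length.
#' @return integer distance.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming(): sequences must have equal length")
  }
  sum(charToRaw(a) != charToRaw(b))
}

# Vectorized Hamming distance of many sequences (equal fixed length) against
# one target. Any position where characters differ counts, so N is a mismatch.
hamming_to <- function(seqs, target) {
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  L <- nchar(target)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  t_chars <- strsplit(target, "", fixed = TRUE)[[1]]
  rowSums(m != matrix(t_chars, nrow = n, ncol = L, byrow = TRUE))
}

# Does concrete base `base` satisfy IUPAC code `code`?
iupac_match_base <- function(base, code) {
  exp <- IUPAC_EXPAND[code]
  !is.na(exp) & vapply(seq_along(base), function(i) {
    grepl(base[i], exp[i], fixed = TRUE)
  }, logical(1))
}

# Locate an IUPAC-degenerate anchor in a concrete sequence, tolerating up to
# max_mismatch non-degenerate mismatches. Returns 1-based start of the best
# (fewest-mismatch) hit, or NA if none within tolerance; ties -> leftmost.
locate_anchor <- function(anchor, seq, max_mismatch = 1L) {
  anchor <- normalize_seq(anchor)
  seq <- normalize_seq(seq)
  la <- nchar(anchor)
  ls <- nchar(seq)
  if (ls < la) return(NA_integer_)
  a_chars <- strsplit(anchor, "", fixed = TRUE)[[1]]
  s_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  allowed <- IUPAC_EXPAND[a_chars]
  best_pos <- NA_integer_
  best_mm <- max_mismatch + 1L
  for (i in seq_len(ls - la + 1L)) {
    window <- s_chars[i:(i + la - 1L)]
    mm <- sum(!vapply(seq_len(la), function(j) {
      grepl(window[j], allowed[j], fixed = TRUE)
    }, logical(1)))
    if (mm < best_mm) {
      best_mm <- mm
      best_pos <- i
    }
  }
  if (best_mm > max_mismatch) NA_integer_ else best_pos
}

# Random DNA of given lengths using the session RNG.
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Round half away from zero to `digits` decimals (presentation rounding for
# frequency tables; base round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
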