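# Fixed nucleotide order used for every matrix in the package.
DNA_BASES <- c("A", "T", "G", "C")

# Dinucleotide order: first base varies slowest, both in A,T,G,C order, i.e.
# AA, AT, AG, AC, TA, TT, TG, TC, GA, GT, GG, GC, CA, CT, CG, CC.
DINUCLEOTIDES <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, times = 4L))

#' Encode DNA strings as a base-index matrix
#'
#' Rows are sequences, columns are positions; entries are indices into
#' the fixed base order A, T, G, C.
#'
#' @param sequences character vector of equal-length DNA strings over
#'   \{A,C,G,T\}.
#' @return integer matrix, `length(sequences)` rows.
#' @keywords internal
#' @noRd
encode_base_matrix <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences to encode")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("sequences must have equal length")
  chars <- strsplit(sequences, "", fixed = TRUE)
  idx <- match(unlist(chars), DNA_BASES)
  if (anyNA(idx)) {
    bad <- unique(unlist(chars)[is.na(match(unlist(chars), DNA_BASES))])
    stop("invalid nucleotide(s): ", paste(bad, collapse = ", "))
  }
  matrix(idx, nrow = length(sequences), ncol = len, byrow = TRUE)
}

# Dinucleotide index from a pair of base indices (both 1..4): 1..16 in the
# fixed order above.
dinuc_index <- function(b1, b2) 4L * (b1 - 1L) + b2

#' Map a DNA string to its overlapping dinucleotide indices
#'
#' Overlapping pairs (positions i, i+1) are mapped to indices 1..16 in the
#' fixed order AA, AT, AG, AC, TA, TT, TG, TC, GA, GT, GG, GC, CA, CT, CG,
#' CC. The output has length `nchar(seq) - 1`.
#'
#' @param seq a single DNA string of length >= 2 over \{A,C,G,T\}.
#' @return named integer vector of dinucleotide indices (1-based).
#' @examples
#' dinucleotide_sequence("AAT")  # AA, AT -> 1, 2
#' @export
dinucleotide_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L) stop("sequence must have length >= 2")
  b <- encode_base_matrix(seq)[1L, ]
  n <- length(b)
  d <- dinuc_index(b[-n], b[-1L])
  names(d) <- DINUCLEOTIDES[d]
  d
}

# Dinucleotide-index matrix for a base-index matrix (rows sequences).
encode_dinuc_matrix <- function(base_mat) {
  n <- ncol(base_mat)
  if (n < 2L) stop("sequences must have length >= 2")
  dinuc_index(base_mat[, -n, drop = FALSE], base_mat[, -1L, drop = FALSE])
}
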