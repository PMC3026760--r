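#' @import methods
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases, converts U to T and rejects anything outside \{A,C,G,T\}.
#' Ambiguity codes are not accepted: exact matching downstream requires a
#' clean alphabet.
#'
#' @param x character scalar, nucleotide sequence.
#' @param allowN logical; when TRUE, N is tolerated (raw reads only).
#' @return normalized character scalar.
#' @keywords internal
normalizeNt <- function(x, allowN = FALSE) {
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string")
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  alphabet <- if (allowN) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nzchar(bad))
    stop("sequence contains characters outside {", alphabet, "}: '",
         substr(bad, 1L, 10L), "'")
  x
}

#' Reverse complement of character nucleotide sequences
#'
#' Thin vectorized wrapper over [Biostrings::reverseComplement()].
#'
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## split a sequence into consecutive codons starting at `offset` (0-based)
codonsFrom <- function(seq, offset) {
  L <- nchar(seq)
  starts <- seq.int(offset + 1L, L, by = 3L)
  starts <- starts[starts + 2L <= L]
  if (length(starts) == 0L) return(character(0))
  substring(seq, starts, starts + 2L)
}

## deterministic child seed derivation; keeps results below .Machine$integer.max
deriveSeed <- function(seed, salt) {
  (as.integer(seed) * 1103L + as.integer(salt) * 12289L) %% 2147483587L
}
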