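# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Accepts gap characters (`-`) and `N`; both are preserved (gaps stay gaps,
#' `N` complements to `N`).
#'
#' @param x A single DNA string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Reverse complement of a character vector of single bases.
revcomp_chars <- function(v) {
  rev(chartr("ACGTN", "TGCAN", v))
}

flip_strand <- function(s) {
  ifelse(s == "+", "-", "+")
}

# Compose a strand with the orientation of a second frame of reference:
# identity when `ref` is "+", flipped when "-".
compose_strand <- function(s, ref) {
  ifelse(ref == "+", s, flip_strand(s))
}

# Split a DNA string into consecutive codons (drops a trailing partial codon).
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sanitize a DNA string: uppercase, anything outside {A,C,G,T,N} becomes N.
clean_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Extract the strand-oriented sequence of [start, end) (0-based half-open)
# from a contig string.
extract_oriented <- function(contig_seq, start, end, strand) {
  s <- substr(contig_seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

stop2 <- function(...) stop(..., call. = FALSE)
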