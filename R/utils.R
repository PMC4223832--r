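#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N,
#' case-insensitive; output uppercase).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Canonical (strand-folded) form of a spacer sequence
#'
#' The canonical form is the lexicographic minimum of a sequence and its
#' reverse complement, so that the same spacer read from either strand maps
#' to one key. Idempotent: `canonical_spacer(canonical_spacer(s)) ==
#' canonical_spacer(s)`.
#'
#' @param x character vector of sequences.
#' @return character vector of canonical sequences.
#' @export
canonical_spacer <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- toupper(x)
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); N and other symbols are excluded from the
#' denominator.
#'
#' @param x a single sequence string.
#' @return fraction in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  stopifnot(length(x) == 1L)
  x <- toupper(x)
  n <- nchar(x)
  if (n == 0L) stop("empty region")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("region contains no A/C/G/T bases")
  sum(chars %in% c("G", "C")) / acgt
}

# Proportion of identical positions between two strings aligned at their left
# ends, divided by the longer length. Cheap similarity used for spacer
# self-similarity screening (tandem-repeat rejection), not an aligner.
string_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- min(length(ca), length(cb))
  sum(ca[seq_len(n)] == cb[seq_len(n)]) / max(length(ca), length(cb))
}

# Hamming distance between equal-length strings.
hamming_dist <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

#' Random nucleotide sequence at a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2. Uses the current RNG stream.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return a single sequence string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Encode a sequence as integers A=0 C=1 G=2 T=3, NA for anything else.
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

# substring() wrapper on 0-based half-open coordinates.
subseq0 <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}
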