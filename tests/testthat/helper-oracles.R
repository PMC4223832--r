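# Independent reference implementations used to cross-check the package.
# These are deliberately naive (character-level sliding comparisons and
# textbook dynamic programming) and share no code with the implementation.

# All maximal exact common substrings of length >= min_len between query q
# (on the given strand of the target) and target t. Returns a data.frame
# with 1-based qstart/tstart and length; `strand` records whether q or its
# reverse complement was compared.
oracle_spans_one_strand <- function(q, t, min_len) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  nq <- length(qc); nt <- length(tc)
  eq <- outer(qc, tc, "==")
  hits <- which(eq, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(qstart = integer(0), tstart = integer(0), len = integer(0)))
  }
  d <- hits[, 2] - hits[, 1]
  out <- list()
  for (dv in unique(d)) {
    rows <- sort(hits[d == dv, 1])
    if (length(rows) < min_len) next
    # maximal runs of consecutive rows
    brk <- c(0, which(diff(rows) != 1), length(rows))
    for (k in seq_len(length(brk) - 1)) {
      run <- rows[(brk[k] + 1):brk[k + 1]]
      if (length(run) >= min_len) {
        out[[length(out) + 1]] <- data.frame(
          qstart = run[1], tstart = run[1] + dv, len = length(run))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(qstart = integer(0), tstart = integer(0), len = integer(0)))
  }
  do.call(rbind, out)
}

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), ""))
}

# Perfect full-length occurrences of spacer (either strand) in target:
# data.frame(strand, offset0).
oracle_perfect <- function(spacer, target) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else oracle_revcomp(spacer)
    L <- nchar(q)
    nt <- nchar(target)
    if (nt < L) next
    for (off in 0:(nt - L)) {
      if (substr(target, off + 1, off + L) == q) {
        out[[length(out) + 1]] <- data.frame(strand = strand, offset0 = off)
      }
    }
  }
  if (length(out) == 0) return(data.frame(strand = character(0), offset0 = integer(0)))
  do.call(rbind, out)
}

# Maximal exact spans >= min_len of spacer (either strand) vs target,
# excluding full-coverage spans: data.frame(strand, offset0, len).
oracle_partial <- function(spacer, target, min_len = 18) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else oracle_revcomp(spacer)
    sp <- oracle_spans_one_strand(q, target, min_len)
    sp <- sp[sp$len < nchar(q), , drop = FALSE]
    if (nrow(sp) > 0) {
      out[[length(out) + 1]] <- data.frame(strand = strand,
                                           offset0 = sp$tstart - 1, len = sp$len)
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(0), offset0 = integer(0), len = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$strand, df$offset0, df$len), , drop = FALSE]
}

# Longest common substring length between two strings (both given strands).
oracle_longest_common_substring <- function(a, b) {
  sp <- oracle_spans_one_strand(a, b, 1)
  if (nrow(sp) == 0) 0L else max(sp$len)
}

# Textbook LCS length over token vectors.
oracle_lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L else max(d[i, j + 1], d[i + 1, j])
  }
  d[n + 1, m + 1]
}
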