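#' Detection parameters for repeat-spacer arrays
#'
#' Defaults are package choices tuned to approximate a CRISPRFinder-style
#' "confirmed" call: repeats 21-48 nt (observed subtype means in Salinispora
#' are 29-37 nt, comfortably inside the window), spacers 0.6-2.5x the repeat
#' length, at least 3 repeat occurrences for a confirmed call, >= 80%
#' occurrence-vs-consensus identity, <= 80% mean pairwise spacer
#' self-identity (rejects tandem repeats), and assembly-gap merging across
#' N-runs up to 2 kb.
#'
#' @param seed_k exact k-mer seed length (nt).
#' @param repeat_len_min,repeat_len_max admissible repeat length (nt).
#' @param spacer_min_frac,spacer_max_frac admissible spacer length as a
#'   fraction of the repeat length.
#' @param min_repeats_confirmed minimum repeat occurrences for "confirmed".
#' @param repeat_identity_min minimum occurrence-vs-consensus identity.
#' @param max_spacer_self_identity maximum mean pairwise spacer identity.
#' @param merge_gap_max maximum N-run gap for locus merging (nt).
#' @return a `detection_config` list.
#' @export
detection_config <- function(seed_k = 16L,
                             repeat_len_min = 21L, repeat_len_max = 48L,
                             spacer_min_frac = 0.6, spacer_max_frac = 2.5,
                             min_repeats_confirmed = 3L,
                             repeat_identity_min = 0.8,
                             max_spacer_self_identity = 0.8,
                             merge_gap_max = 2000L) {
  stopifnot(repeat_len_min <= repeat_len_max,
            spacer_min_frac > 0, spacer_max_frac >= spacer_min_frac,
            repeat_identity_min > 0, repeat_identity_min <= 1,
            max_spacer_self_identity > 0, max_spacer_self_identity <= 1)
  structure(list(seed_k = as.integer(seed_k),
                 repeat_len_min = as.integer(repeat_len_min),
                 repeat_len_max = as.integer(repeat_len_max),
                 spacer_min_frac = spacer_min_frac,
                 spacer_max_frac = spacer_max_frac,
                 min_repeats_confirmed = as.integer(min_repeats_confirmed),
                 repeat_identity_min = repeat_identity_min,
                 max_spacer_self_identity = max_spacer_self_identity,
                 merge_gap_max = as.integer(merge_gap_max)),
            class = "detection_config")
}

spacer_bounds <- function(rep_len, cfg) {
  c(max(1L, as.integer(floor(cfg$spacer_min_frac * rep_len))),
    as.integer(ceiling(cfg$spacer_max_frac * rep_len)))
}

period_bounds <- function(cfg) {
  c(as.integer(floor(cfg$repeat_len_min * (1 + cfg$spacer_min_frac))),
    as.integer(ceiling(cfg$repeat_len_max * (1 + cfg$spacer_max_frac))))
}

# Locus constructor from repeat occurrence starts (1-based) and repeat length,
# on one contig. Computes repeats, spacers, consensus and per-occurrence
# identity; coordinates emitted 0-based half-open.
build_locus <- function(seq, starts, rep_len, strain_id, contig_id) {
  starts <- sort(starts)
  reps <- substring(seq, starts, starts + rep_len - 1L)
  cons <- repeat_consensus(reps)
  occ_id <- vapply(reps, function(r) 1 - hamming_dist(r, cons$consensus) / rep_len, 0)
  n <- length(starts)
  sp_start <- if (n > 1L) starts[-n] + rep_len - 1L else integer(0)  # 0-based
  sp_end <- if (n > 1L) starts[-1L] - 1L else integer(0)             # half-open end
  structure(list(
    locus_id = NA_character_,
    strain_id = strain_id,
    contig_id = contig_id,
    start = starts[1L] - 1L,
    end = starts[n] + rep_len - 1L,
    repeat_starts = starts - 1L,
    repeat_ends = starts + rep_len - 1L,
    spacer_starts = sp_start,
    spacer_ends = sp_end,
    repeats = unname(reps),
    spacers = if (n > 1L) substring(seq, sp_start + 1L, sp_end) else character(0),
    consensus = cons$consensus,
    repeat_freq = cons$freq,
    repeat_len_mean = rep_len,
    occ_identity = unname(occ_id),
    orientation = "unknown",
    confidence = NA_character_,
    cas_associated = FALSE,
    cluster_id = NA_character_,
    subtype_context = NA_character_,
    merged_from = character(0)
  ), class = "crispr_locus")
}

# Exact k-mer anchors: (position, period) pairs where a seed k-mer recurs at
# a spacing compatible with one repeat-spacer period.
kmer_anchors <- function(codes, cfg) {
  k <- cfg$seed_k
  n <- length(codes)
  pb <- period_bounds(cfg)
  if (n < k + pb[1L]) return(data.frame(pos = integer(0), period = integer(0)))
  m <- n - k + 1L
  val <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in 0:(k - 1L)) {
    cj <- codes[(1L + j):(m + j)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 0L
    val <- val * 4 + cj
  }
  pos <- which(ok)
  if (length(pos) < 2L) return(data.frame(pos = integer(0), period = integer(0)))
  vv <- val[pos]
  ord <- order(vv, pos)
  v <- vv[ord]; p <- pos[ord]
  same <- diff(v) == 0
  d <- diff(p)
  sel <- same & d >= pb[1L] & d <= pb[2L]
  data.frame(pos = p[-length(p)][sel], period = d[sel])
}

# Occurrences of repeat R0 within a window, allowing mismatches up to the
# identity threshold; near-duplicate starts collapsed to the best one.
find_occurrences <- function(seq, R0, cfg, win) {
  L <- nchar(R0)
  sub <- substring(seq, win[1L], win[2L])
  maxmm <- as.integer(floor((1 - cfg$repeat_identity_min) * L))
  m <- Biostrings::matchPattern(Biostrings::DNAString(R0), Biostrings::DNAString(sub),
                                max.mismatch = maxmm, with.indels = FALSE)
  if (length(m) == 0L) return(integer(0))
  starts <- BiocGenerics::start(m) + win[1L] - 1L
  occ <- substring(seq, starts, starts + L - 1L)
  mm <- vapply(occ, function(o) hamming_dist(o, R0), 0L)
  ord <- order(starts)
  starts <- starts[ord]; mm <- mm[ord]
  # collapse starts closer than half a repeat length
  keep <- logical(length(starts))
  i <- 1L
  while (i <= length(starts)) {
    j <- i
    while (j < length(starts) && starts[j + 1L] - starts[j] < max(1L, L %/% 2L)) j <- j + 1L
    grp <- i:j
    best <- grp[which.min(mm[grp])]
    keep[best] <- TRUE
    i <- j + 1L
  }
  starts[keep]
}

# Longest run of consecutive occurrences whose inter-occurrence gaps are
# admissible spacer lengths; leftmost run on ties.
chain_occurrences <- function(starts, rep_len, cfg) {
  n <- length(starts)
  if (n < 2L) return(integer(0))
  sb <- spacer_bounds(rep_len, cfg)
  gaps <- starts[-1L] - (starts[-n] + rep_len)
  ok <- gaps >= sb[1L] & gaps <= sb[2L]
  best <- c(0L, 0L)  # length, start index
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      if (j - i + 2L > best[1L]) best <- c(j - i + 2L, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (best[1L] < 2L) return(integer(0))
  best[2L]:(best[2L] + best[1L] - 1L)
}

# Column conservation threshold for boundary decisions: with n occurrences a
# boundary column must reach max(identity_min, 1 - 1/n) agreement, i.e. full
# agreement for small arrays and at most one deviating base for larger ones.
col_thr <- function(n, cfg) max(cfg$repeat_identity_min, 1 - 1 / n)

col_conservation <- function(codes, positions) {
  v <- codes[positions]
  if (any(is.na(v)) || any(positions < 1L)) return(0)
  max(tabulate(v + 1L, nbins = 4L)) / length(v)
}

# Trim boundary columns below the conservation threshold (with a 3-column
# lookahead, so a chance-conserved column cannot shield unconserved columns
# just inside it), then extend boundaries outward while columns stay above
# the threshold (never past length or spacer-length constraints).
refine_boundaries <- function(codes, starts, rep_len, cfg) {
  n <- length(starts)
  thr <- col_thr(n, cfg)
  min_gap_ok <- function(starts, rep_len) {
    if (length(starts) < 2L) return(TRUE)
    sb <- spacer_bounds(rep_len, cfg)
    gaps <- starts[-1L] - (starts[-length(starts)] + rep_len)
    all(gaps >= max(1L, sb[1L]))
  }
  edge_bad <- function(offsets) {
    any(vapply(offsets, function(d) {
      col_conservation(codes, starts + d) < thr
    }, TRUE))
  }
  # trim left: boundary plus the next two columns must all be conserved
  while (rep_len > cfg$repeat_len_min &&
         edge_bad(0:min(2L, rep_len - 1L))) {
    starts <- starts + 1L
    rep_len <- rep_len - 1L
  }
  # trim right
  while (rep_len > cfg$repeat_len_min &&
         edge_bad(rep_len - 1L - (0:min(2L, rep_len - 1L)))) {
    rep_len <- rep_len - 1L
  }
  # extend only through unanimous columns: a column where one occurrence
  # deviates is indistinguishable from a chance-conserved spacer-edge
  # column, so extension demands full agreement (trimming stays tolerant)
  while (rep_len < cfg$repeat_len_max && starts[1L] > 1L &&
         col_conservation(codes, starts - 1L) >= 1 &&
         min_gap_ok(starts - 1L, rep_len + 1L)) {
    starts <- starts - 1L
    rep_len <- rep_len + 1L
  }
  while (rep_len < cfg$repeat_len_max &&
         starts[length(starts)] + rep_len <= length(codes) &&
         col_conservation(codes, starts + rep_len) >= 1 &&
         min_gap_ok(starts, rep_len + 1L)) {
    rep_len <- rep_len + 1L
  }
  list(starts = starts, rep_len = rep_len)
}

# Build one candidate array from a seed (pos, period).
try_build <- function(seq, codes, pos, period, cfg, win, strain_id, contig_id) {
  k <- cfg$seed_k
  n <- length(codes)
  cap <- min(cfg$repeat_len_max, period - 1L)
  a1 <- pos; a2 <- pos + period
  l <- 0L
  while (k + l < cap && a1 - l - 1L >= 1L) {
    c1 <- codes[a1 - l - 1L]; c2 <- codes[a2 - l - 1L]
    if (is.na(c1) || is.na(c2) || c1 != c2) break
    l <- l + 1L
  }
  r <- 0L
  while (k + l + r < cap && a2 + k + r <= n) {
    c1 <- codes[a1 + k + r]; c2 <- codes[a2 + k + r]
    if (is.na(c1) || is.na(c2) || c1 != c2) break
    r <- r + 1L
  }
  rep_len <- k + l + r
  rstart <- a1 - l
  R0 <- substring(seq, rstart, rstart + rep_len - 1L)
  occ <- find_occurrences(seq, R0, cfg, win)
  idx <- chain_occurrences(occ, rep_len, cfg)
  if (length(idx) < 2L) return(NULL)
  ref <- refine_boundaries(codes, occ[idx], rep_len, cfg)
  if (ref$rep_len < cfg$repeat_len_min || ref$rep_len > cfg$repeat_len_max) return(NULL)
  sb <- spacer_bounds(ref$rep_len, cfg)
  gaps <- diff(ref$starts) - ref$rep_len
  if (length(gaps) && (any(gaps < sb[1L]) || any(gaps > sb[2L]))) return(NULL)
  build_locus(seq, ref$starts, ref$rep_len, strain_id, contig_id)
}

# Deterministic overlap resolution: more repeats, then longer span, then
# leftmost.
resolve_overlaps <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  nrep <- vapply(cands, function(l) length(l$repeat_starts), 0L)
  span <- vapply(cands, function(l) l$end - l$start, 0L)
  st <- vapply(cands, function(l) l$start, 0L)
  ord <- order(-nrep, -span, st)
  cands <- cands[ord]
  kept <- list()
  for (cand in cands) {
    clash <- any(vapply(kept, function(kpt) {
      kpt$contig_id == cand$contig_id && cand$start < kpt$end && kpt$start < cand$end
    }, TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  st2 <- vapply(kept, function(l) l$start, 0L)
  ct <- vapply(kept, function(l) l$contig_id, "")
  kept[order(ct, st2)]
}

scan_contig <- function(seq, cfg, strain_id, contig_id) {
  n <- nchar(seq)
  if (n < 2L * cfg$repeat_len_min) return(list())
  codes <- encode_dna(seq)
  anch <- kmer_anchors(codes, cfg)
  if (nrow(anch) == 0L) return(list())
  pb <- period_bounds(cfg)
  ord <- order(anch$pos)
  anch <- anch[ord, , drop = FALSE]
  cluster_id <- cumsum(c(1L, diff(anch$pos) > 2L * pb[2L]))
  cands <- list()
  for (cl in split(anch, cluster_id)) {
    win <- c(max(1L, min(cl$pos) - pb[2L]),
             min(n, max(cl$pos) + cfg$seed_k + 2L * pb[2L]))
    # seeds: most frequent periods first; first/middle/last anchor of each
    ptab <- sort(table(cl$period), decreasing = TRUE)
    seeds <- list()
    for (pv in as.integer(names(ptab))) {
      rows <- which(cl$period == pv)
      pick <- unique(rows[c(1L, ceiling(length(rows) / 2), length(rows))])
      for (i in pick) seeds[[length(seeds) + 1L]] <- c(cl$pos[i], cl$period[i])
      if (length(seeds) >= 9L) break
    }
    built <- list()
    for (s in seeds) {
      loc <- try_build(seq, codes, s[1L], s[2L], cfg, win, strain_id, contig_id)
      if (!is.null(loc)) {
        key <- paste(loc$repeat_starts, collapse = ",")
        if (is.null(built[[key]])) built[[key]] <- loc
      }
    }
    cands <- c(cands, unname(built))
  }
  resolve_overlaps(cands)
}

#' Detect candidate repeat-spacer arrays in a genome
#'
#' De novo detection by exact k-mer seeding: k-mers recurring at a spacing
#' compatible with one repeat-spacer period anchor candidate arrays, seeds
#' are extended into a candidate repeat, all occurrences within the identity
#' threshold are chained under the spacer-length constraints, and repeat
#' boundaries are refined by per-column conservation. Overlapping candidates
#' are resolved deterministically (more repeats, longer span, leftmost).
#' Every emitted locus is also assigned a confidence class (see
#' [classify_confidence()]).
#'
#' @param genome a `genome_record`.
#' @param cfg a [detection_config()].
#' @return list of `crispr_locus` objects ordered by (contig, start), with
#'   ids `<strain>|<contig>|<k>`. Contigs shorter than twice the minimum
#'   repeat length are skipped.
#' @export
find_candidate_arrays <- function(genome, cfg = detection_config()) {
  loci <- list()
  for (contig_id in names(genome$contigs)) {
    loci <- c(loci, scan_contig(genome$contigs[[contig_id]], cfg,
                                genome$strain_id, contig_id))
  }
  for (i in seq_along(loci)) {
    loci[[i]]$locus_id <- paste(genome$strain_id, loci[[i]]$contig_id, i, sep = "|")
    loci[[i]]$confidence <- classify_confidence(loci[[i]], cfg)
  }
  loci
}

#' Confidence class of a detected locus
#'
#' A locus is `confirmed` iff it has at least `min_repeats_confirmed` repeat
#' occurrences, every occurrence is within `repeat_identity_min` of the
#' consensus, and the mean pairwise spacer self-identity does not exceed
#' `max_spacer_self_identity` (which rejects tandem repeats masquerading as
#' arrays); otherwise `questionable`. Downstream stages consider confirmed
#' loci only.
#'
#' @param locus a `crispr_locus`.
#' @param cfg a [detection_config()].
#' @return `"confirmed"` or `"questionable"`.
#' @export
classify_confidence <- function(locus, cfg = detection_config()) {
  n <- length(locus$repeat_starts)
  if (n < cfg$min_repeats_confirmed) return("questionable")
  if (any(locus$occ_identity < cfg$repeat_identity_min)) return("questionable")
  sp <- locus$spacers
  if (length(sp) >= 2L) {
    pairs <- utils::combn(length(sp), 2L)
    mean_id <- mean(apply(pairs, 2L, function(p) string_identity(sp[p[1L]], sp[p[2L]])))
    if (mean_id > cfg$max_spacer_self_identity) return("questionable")
  }
  "confirmed"
}

#' Merge adjacent loci split by assembly gaps
#'
#' Two neighbouring loci on one contig are combined iff the sequence between
#' them is an N-run (allowing up to 10 non-N bp at each flank) no longer than
#' `merge_gap_max`, and their consensus repeats are identical or exact
#' reverse complements. The gap is retained as a spacer interval of the
#' merged locus (so repeats and spacers still tile the interval); merged loci
#' record their source ids in `merged_from` and are re-classified.
#'
#' @param loci list of `crispr_locus` on one contig, sorted by start.
#' @param contig_seq the contig sequence.
#' @param cfg a [detection_config()].
#' @return list of loci after merging.
#' @export
merge_adjacent_loci <- function(loci, contig_seq, cfg = detection_config()) {
  if (length(loci) <= 1L) return(loci)
  st <- vapply(loci, function(l) l$start, 0L)
  loci <- loci[order(st)]
  out <- list(loci[[1L]])
  for (i in 2:length(loci)) {
    cur <- out[[length(out)]]
    nxt <- loci[[i]]
    gap_seq <- subseq0(contig_seq, cur$end, nxt$start)
    if (is_n_gap(gap_seq, cfg$merge_gap_max) &&
        (cur$consensus == nxt$consensus || cur$consensus == revcomp(nxt$consensus))) {
      merged <- merge_pair(cur, nxt, gap_seq)
      merged$confidence <- classify_confidence(merged, cfg)
      out[[length(out)]] <- merged
    } else {
      out[[length(out) + 1L]] <- nxt
    }
  }
  out
}

is_n_gap <- function(gap_seq, gap_max) {
  ln <- nchar(gap_seq)
  if (ln == 0L || ln > gap_max) return(FALSE)
  core <- sub("^[ACGT]{0,10}", "", gap_seq)
  core <- sub("[ACGT]{0,10}$", "", core)
  nchar(core) > 0L && !grepl("[^N]", core)
}

merge_pair <- function(a, b, gap_seq) {
  m <- a
  m$end <- b$end
  m$repeat_starts <- c(a$repeat_starts, b$repeat_starts)
  m$repeat_ends <- c(a$repeat_ends, b$repeat_ends)
  m$repeats <- c(a$repeats, b$repeats)
  m$spacer_starts <- c(a$spacer_starts, a$end, b$spacer_starts)
  m$spacer_ends <- c(a$spacer_ends, b$start, b$spacer_ends)
  m$spacers <- c(a$spacers, gap_seq, b$spacers)
  cons <- repeat_consensus(m$repeats)
  m$consensus <- cons$consensus
  m$repeat_freq <- cons$freq
  m$repeat_len_mean <- mean(nchar(m$repeats))
  m$occ_identity <- vapply(m$repeats, function(r) string_identity(r, m$consensus), 0,
                           USE.NAMES = FALSE)
  m$merged_from <- c(if (length(a$merged_from)) a$merged_from else a$locus_id,
                     if (length(b$merged_from)) b$merged_from else b$locus_id)
  m
}

#' Assign the leader/trailer orientation of a locus
#'
#' The leader end (where new spacers are integrated) is placed on the side
#' adjacent to an associated cas cluster when one is known. Without a cas
#' signal, a degenerate terminal repeat marks the trailer: if one terminal
#' occurrence has consensus identity lower than the other terminal by more
#' than `margin`, the leader is the opposite side. With neither signal the
#' orientation is `unknown`.
#'
#' @param locus a `crispr_locus`.
#' @param cas_side `"left"`, `"right"` or `NULL`.
#' @param margin minimum terminal identity difference for the degenerate-
#'   repeat signal.
#' @return the locus with `orientation` set to `leader_left`, `leader_right`
#'   or `unknown`.
#' @export
orient_locus <- function(locus, cas_side = NULL, margin = 0.05) {
  if (!is.null(cas_side)) {
    locus$orientation <- if (cas_side == "left") "leader_left" else "leader_right"
    return(locus)
  }
  ids <- locus$occ_identity
  n <- length(ids)
  if (n >= 2L) {
    if (ids[1L] < ids[n] - margin) {
      locus$orientation <- "leader_right"   # degenerate (trailer) repeat left
      return(locus)
    }
    if (ids[n] < ids[1L] - margin) {
      locus$orientation <- "leader_left"
      return(locus)
    }
  }
  locus$orientation <- "unknown"
  locus
}

#' Find paired loci flanking internal cas clusters
#'
#' A pair is two confirmed loci flanking one cas cluster, each within
#' `max_distance` edge-to-edge, whose consensus repeats are exact reverse
#' complements of each other (one array inverted).
#'
#' @param loci list of `crispr_locus`.
#' @param clusters list of `cas_cluster` objects.
#' @param max_distance maximum edge-to-edge distance (nt).
#' @return data.frame with columns `cluster_id`, `left_locus`, `right_locus`.
#' @export
detect_paired_loci <- function(loci, clusters, max_distance = 1000L) {
  out <- data.frame(cluster_id = character(0), left_locus = character(0),
                    right_locus = character(0), stringsAsFactors = FALSE)
  for (cl in clusters) {
    same <- Filter(function(l) l$strain_id == cl$strain_id &&
                     l$contig_id == cl$contig_id &&
                     l$confidence == "confirmed", loci)
    lefts <- Filter(function(l) l$end <= cl$start &&
                      cl$start - l$end <= max_distance, same)
    rights <- Filter(function(l) l$start >= cl$end &&
                       l$start - cl$end <= max_distance, same)
    for (lf in lefts) for (rt in rights) {
      if (lf$consensus == revcomp(rt$consensus)) {
        out <- rbind(out, data.frame(cluster_id = cl$cluster_id,
                                     left_locus = lf$locus_id,
                                     right_locus = rt$locus_id,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Majority-vote repeat consensus with a base frequency table
#'
#' Occurrences are trimmed (or right-padded with N) to the modal length; at
#' each position the most frequent base wins, with ties broken by the fixed
#' base order A < C < G < T. N contributes to the frequency table (rows sum
#' to the occurrence count) but never wins a majority unless a column is all
#' N.
#'
#' @param occurrences character vector of repeat occurrence sequences
#'   (>= 2).
#' @return list with `consensus` (string) and `freq` (positions x A,C,G,T,N
#'   count matrix).
#' @export
repeat_consensus <- function(occurrences) {
  stopifnot(length(occurrences) >= 2L)
  lens <- nchar(occurrences)
  tl <- table(lens)
  modal <- min(as.integer(names(tl)[tl == max(tl)]))
  padded <- vapply(occurrences, function(o) {
    if (nchar(o) >= modal) substr(o, 1L, modal)
    else paste0(o, strrep("N", modal - nchar(o)))
  }, "", USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(padded, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T", "N")
  freq <- t(apply(mat, 2L, function(col) {
    vapply(bases, function(b) sum(col == b), 0L)
  }))
  colnames(freq) <- bases
  cons <- apply(freq, 1L, function(row) {
    acgt <- row[1:4]
    if (all(acgt == 0L)) return("N")
    bases[which.max(acgt)]  # which.max takes the first (A<C<G<T) on ties
  })
  list(consensus = paste(cons, collapse = ""), freq = freq)
}

#' Exhaustive array scanner (reference implementation)
#'
#' Tests every (start, period) position pair with an exactly repeated unit of
#' admissible length, chains exact occurrences under the same spacer-length
#' constraints as the seeded detector, and applies the same boundary
#' refinement, acceptance rules and overlap resolution. Quadratic; intended
#' for cross-checking the seeded detector on sequences up to a few kb.
#'
#' @param seq a contig sequence.
#' @param cfg a [detection_config()].
#' @param strain_id,contig_id identifiers for the emitted loci.
#' @return list of `crispr_locus` objects.
#' @export
brute_force_scan <- function(seq, cfg = detection_config(),
                             strain_id = "strain", contig_id = "contig") {
  n <- nchar(seq)
  codes <- encode_dna(seq)
  pb <- period_bounds(cfg)
  cands <- list()
  for (d in pb[1L]:pb[2L]) {
    if (n - d < cfg$repeat_len_min) next
    eq <- codes[1:(n - d)] == codes[(1 + d):n]
    eq[is.na(eq)] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= cfg$repeat_len_min)
    for (ri in runs) {
      s <- starts[ri]
      rep_len <- min(r$lengths[ri], cfg$repeat_len_max, d - 1L)
      if (rep_len < cfg$repeat_len_min) next
      R <- substring(seq, s, s + rep_len - 1L)
      occ <- s
      # walk forward: next exact occurrence at an admissible spacer distance
      sb <- spacer_bounds(rep_len, cfg)
      repeat {
        last <- occ[length(occ)]
        lo <- last + rep_len + sb[1L]; hi <- min(n - rep_len + 1L, last + rep_len + sb[2L])
        if (lo > hi) break
        found <- NA_integer_
        for (t in lo:hi) {
          if (substring(seq, t, t + rep_len - 1L) == R) { found <- t; break }
        }
        if (is.na(found)) break
        occ <- c(occ, found)
      }
      # walk backward
      repeat {
        first <- occ[1L]
        hi <- first - rep_len - sb[1L]; lo <- max(1L, first - rep_len - sb[2L])
        if (hi < lo) break
        found <- NA_integer_
        for (t in hi:lo) {
          if (substring(seq, t, t + rep_len - 1L) == R) { found <- t; break }
        }
        if (is.na(found)) break
        occ <- c(found, occ)
      }
      if (length(occ) < 2L) next
      ref <- refine_boundaries(codes, occ, rep_len, cfg)
      if (ref$rep_len < cfg$repeat_len_min || ref$rep_len > cfg$repeat_len_max) next
      loc <- build_locus(seq, ref$starts, ref$rep_len, strain_id, contig_id)
      key <- paste(loc$repeat_starts, collapse = ",")
      if (is.null(cands[[key]])) cands[[key]] <- loc
    }
  }
  out <- resolve_overlaps(unname(cands))
  for (i in seq_along(out)) {
    out[[i]]$locus_id <- paste(strain_id, contig_id, i, sep = "|")
    out[[i]]$confidence <- classify_confidence(out[[i]], cfg)
  }
  out
}

#' Tabulate loci scalars
#'
#' @param loci list of `crispr_locus` objects.
#' @return one row per locus with id, coordinates, repeat/spacer counts,
#'   consensus, orientation, confidence and cas association.
#' @export
loci_table <- function(loci) {
  if (length(loci) == 0L) {
    return(data.frame(locus_id = character(0), strain_id = character(0),
                      contig_id = character(0), start = integer(0), end = integer(0),
                      n_repeats = integer(0), n_spacers = integer(0),
                      repeat_len = numeric(0), locus_size = integer(0),
                      consensus = character(0), orientation = character(0),
                      confidence = character(0), cas_associated = logical(0),
                      cluster_id = character(0), subtype = character(0),
                      merged_from = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(loci, function(l) data.frame(
    locus_id = l$locus_id, strain_id = l$strain_id, contig_id = l$contig_id,
    start = l$start, end = l$end,
    n_repeats = length(l$repeat_starts), n_spacers = length(l$spacer_starts),
    repeat_len = l$repeat_len_mean, locus_size = l$end - l$start,
    consensus = l$consensus, orientation = l$orientation,
    confidence = l$confidence, cas_associated = l$cas_associated,
    cluster_id = l$cluster_id, subtype = l$subtype_context,
    merged_from = paste(l$merged_from, collapse = ","),
    stringsAsFactors = FALSE)))
  df <- df[order(df$strain_id, df$contig_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
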