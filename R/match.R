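empty_hits <- function() {
  data.frame(spacer_id = character(0), target_id = character(0),
             target_class = character(0), strand = character(0),
             target_offset = integer(0), match_length = integer(0),
             category = character(0), stringsAsFactors = FALSE)
}

as_spacer_vec <- function(spacers) {
  if (is.data.frame(spacers)) {
    v <- toupper(spacers$sequence)
    names(v) <- spacers$spacer_id
    v
  } else {
    v <- toupper(spacers)
    if (is.null(names(v))) names(v) <- paste0("spacer", seq_along(v))
    v
  }
}

as_target_df <- function(targets) {
  if (is.data.frame(targets)) {
    id <- if ("region_id" %in% names(targets)) targets$region_id else targets$id
    data.frame(target_id = id, sequence = toupper(targets$sequence),
               class = if ("class" %in% names(targets)) targets$class else "target",
               stringsAsFactors = FALSE)
  } else {
    data.frame(target_id = names(targets) %||% paste0("target", seq_along(targets)),
               sequence = toupper(targets), class = "target",
               stringsAsFactors = FALSE)
  }
}

#' Perfect spacer-protospacer matches
#'
#' Reports every occurrence of a spacer, or of its reverse complement, as an
#' exact full-length substring of any target (100% identity over the entire
#' spacer length). Because only ungapped 100%-identity full-coverage hits are
#' counted, exact substring search returns the same hit set as a short-query
#' BLAST (word size 7) followed by a 100% identity/coverage filter: any exact
#' span of length L >= 7 necessarily contains an exact word of length 7, so
#' seeding loses nothing, and the post-filter discards everything else.
#'
#' @param spacers spacer record data.frame (columns `spacer_id`, `sequence`)
#'   or named character vector; spacers must be >= 18 nt.
#' @param targets target data.frame (columns `region_id`/`id`, `sequence`,
#'   optional `class`) or named character vector.
#' @return hit data.frame (`spacer_id`, `target_id`, `target_class`,
#'   `strand`, `target_offset` 0-based, `match_length`, `category =
#'   "perfect"`), ordered by (spacer_id, target_id, offset). Strand `-`
#'   means the reverse complement of the spacer matched the target as
#'   written.
#' @export
perfect_match <- function(spacers, targets) {
  sp <- as_spacer_vec(spacers)
  tg <- as_target_df(targets)
  if (length(sp) == 0L || nrow(tg) == 0L) return(empty_hits())
  if (any(nchar(sp) < 18L)) stop("spacers must be at least 18 nt")
  uniq <- unique(unname(sp))
  # seed on the first 18 nt of each query strand, verify full length
  qtab <- data.frame(q = rep(uniq, 2L),
                     strand = rep(c("+", "-"), each = length(uniq)),
                     stringsAsFactors = FALSE)
  qtab$pat <- ifelse(qtab$strand == "+", qtab$q, revcomp(qtab$q))
  pd <- Biostrings::PDict(substr(qtab$pat, 1L, 18L))
  out <- list()
  for (t in seq_len(nrow(tg))) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(tg$sequence[t]))
    starts <- Biostrings::startIndex(m)
    tlen <- nchar(tg$sequence[t])
    for (qi in seq_len(nrow(qtab))) {
      ss <- starts[[qi]]
      if (is.null(ss) || length(ss) == 0L) next
      L <- nchar(qtab$pat[qi])
      for (s in ss) {
        if (s + L - 1L > tlen) next
        if (substr(tg$sequence[t], s, s + L - 1L) != qtab$pat[qi]) next
        ids <- names(sp)[sp == qtab$q[qi]]
        for (id in ids) {
          out[[length(out) + 1L]] <- data.frame(
            spacer_id = id, target_id = tg$target_id[t],
            target_class = tg$class[t], strand = qtab$strand[qi],
            target_offset = s - 1L, match_length = L,
            category = "perfect", stringsAsFactors = FALSE)
        }
      }
    }
  }
  finish_hits(out)
}

finish_hits <- function(rows) {
  if (length(rows) == 0L) return(empty_hits())
  df <- do.call(rbind, rows)
  df <- df[order(df$spacer_id, df$target_id, df$strand, df$target_offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Maximal exact diagonal extension of a seed match between query and target.
extend_diagonal <- function(q, t, qoff, toff) {
  nq <- nchar(q); nt <- nchar(t)
  l <- 0L
  while (qoff - l - 1L >= 1L && toff - l - 1L >= 1L &&
         substr(q, qoff - l - 1L, qoff - l - 1L) == substr(t, toff - l - 1L, toff - l - 1L)) {
    l <- l + 1L
  }
  r <- 0L
  while (qoff + r <= nq && toff + r <= nt &&
         substr(q, qoff + r, qoff + r) == substr(t, toff + r, toff + r)) {
    r <- r + 1L
  }
  c(qstart = qoff - l, tstart = toff - l, len = l + r)
}

#' Partial spacer-protospacer matches
#'
#' Maximal exact common substrings of length at least `min_len` (default
#' 18 nt, i.e. two thirds of the average Salinispora repeat length) between a
#' spacer (either strand) and a target, at 100% identity within the matched
#' span. Spans covered by a perfect full-coverage hit are excluded, so
#' `category = "partial"` always has `min_len <= match_length < spacer
#' length`. Each maximal span is reported once.
#'
#' @inheritParams perfect_match
#' @param min_len minimum span length (nt).
#' @return hit data.frame as in [perfect_match()] with `category =
#'   "partial"`.
#' @export
partial_match <- function(spacers, targets, min_len = 18L) {
  sp <- as_spacer_vec(spacers)
  tg <- as_target_df(targets)
  if (length(sp) == 0L || nrow(tg) == 0L) return(empty_hits())
  if (any(nchar(sp) < min_len)) stop("spacers must be at least min_len nt")
  uniq <- unique(unname(sp))
  # one seed per query offset and strand, indexed jointly; each seed hit is
  # extended to the maximal exact span on its diagonal, then deduplicated
  qs <- c(uniq, revcomp(uniq))
  qstrand <- rep(c("+", "-"), each = length(uniq))
  qidx <- rep(seq_along(uniq), 2L)
  n_off <- nchar(qs) - min_len + 1L
  seeds <- data.frame(
    qi = rep(qidx, n_off),
    strand = rep(qstrand, n_off),
    off = unlist(lapply(n_off, seq_len), use.names = FALSE),
    q = rep(qs, n_off),
    stringsAsFactors = FALSE
  )
  seeds$seed <- substr(seeds$q, seeds$off, seeds$off + min_len - 1L)
  pd <- Biostrings::PDict(seeds$seed)
  out <- list()
  for (t in seq_len(nrow(tg))) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(tg$sequence[t]))
    starts <- Biostrings::startIndex(m)
    nhit <- vapply(starts, length, 0L)
    if (sum(nhit) == 0L) next
    idx <- rep(seq_len(nrow(seeds)), nhit)
    pos <- unlist(starts, use.names = FALSE)
    spans <- new.env(parent = emptyenv())
    for (k in seq_along(idx)) {
      srow <- idx[k]
      ext <- extend_diagonal(seeds$q[srow], tg$sequence[t], seeds$off[srow], pos[k])
      key <- paste(seeds$qi[srow], seeds$strand[srow], ext["tstart"], ext["len"], sep = "|")
      if (is.null(spans[[key]])) {
        spans[[key]] <- c(qi = seeds$qi[srow], tstart = unname(ext["tstart"]),
                          len = unname(ext["len"]),
                          minus = as.integer(seeds$strand[srow] == "-"))
      }
    }
    for (key in ls(spans)) {
      svec <- spans[[key]]
      L <- nchar(uniq[svec["qi"]])
      if (svec["len"] >= L) next  # full coverage = perfect, not partial
      if (svec["len"] < min_len) next
      ids <- names(sp)[sp == uniq[svec["qi"]]]
      for (id in ids) {
        out[[length(out) + 1L]] <- data.frame(
          spacer_id = id, target_id = tg$target_id[t],
          target_class = tg$class[t],
          strand = if (svec["minus"] == 1L) "-" else "+",
          target_offset = unname(svec["tstart"]) - 1L,
          match_length = unname(svec["len"]),
          category = "partial", stringsAsFactors = FALSE)
      }
    }
  }
  finish_hits(out)
}

#' Scan a strain's own genome for self-targeting spacers
#'
#' Perfect (and optionally partial) hits of each of the strain's spacers
#' against its own contigs, excluding hits that overlap any detected CRISPR
#' locus interval expanded by `margin` nt (a spacer trivially matches its
#' own array). Hits overlapping annotated prophage regions are flagged
#' `overlaps_prophage`.
#'
#' @param genome a `genome_record`.
#' @param loci the strain's detected loci.
#' @param records the strain's spacer records ([extract_spacers()]).
#' @param prophages optional prophage region table with on-contig
#'   coordinates (`contig_id`, `start`, `end`).
#' @param margin exclusion margin around loci (nt).
#' @param include_partial also report partial self hits.
#' @param min_len minimum partial span (nt).
#' @return hit data.frame with `target_class = "self"` plus
#'   `overlaps_prophage` and `in_crispr_locus` flags (the latter always
#'   FALSE after exclusion).
#' @export
self_targeting_scan <- function(genome, loci, records, prophages = NULL,
                                margin = 100L, include_partial = FALSE,
                                min_len = 18L) {
  records <- records[records$strain_id == genome$strain_id, , drop = FALSE]
  targets <- data.frame(region_id = names(genome$contigs),
                        sequence = unname(genome$contigs),
                        class = "self", stringsAsFactors = FALSE)
  hits <- perfect_match(records, targets)
  if (include_partial) hits <- rbind(hits, partial_match(records, targets, min_len))
  if (nrow(hits) == 0L) {
    hits$overlaps_prophage <- logical(0)
    hits$in_crispr_locus <- logical(0)
    return(hits)
  }
  keep <- rep(TRUE, nrow(hits))
  for (l in loci) {
    if (l$strain_id != genome$strain_id) next
    same <- hits$target_id == l$contig_id
    ov <- same & hits$target_offset < l$end + margin &
      hits$target_offset + hits$match_length > l$start - margin
    keep <- keep & !ov
  }
  hits <- hits[keep, , drop = FALSE]
  hits$overlaps_prophage <- logical(nrow(hits))
  if (!is.null(prophages) && nrow(hits) > 0L) {
    pp <- prophages[!is.na(prophages$contig_id) &
                      prophages$strain_id %in% c(NA, genome$strain_id), , drop = FALSE]
    for (i in seq_len(nrow(pp))) {
      ov <- hits$target_id == pp$contig_id[i] &
        hits$target_offset < pp$end[i] &
        hits$target_offset + hits$match_length > pp$start[i]
      hits$overlaps_prophage <- hits$overlaps_prophage | ov
    }
  }
  hits$in_crispr_locus <- logical(nrow(hits))
  rownames(hits) <- NULL
  hits
}

subtype_family <- function(subtype) {
  ifelse(is.na(subtype) | subtype == "unclassified", NA_character_,
         ifelse(subtype %in% c("I-E", "I-C", "I-B"), "known_subtype", "I-U"))
}

#' Summarise spacer matches by grouping
#'
#' For each group, the percentage of distinct (canonical) spacers with at
#' least one perfect hit against prophages and against known MGEs. A spacer
#' counts once per target class no matter how many targets it hits.
#' Groupings: strain, species, cas association (associated vs devoid), and
#' subtype family (canonical I-E/I-C/I-B vs the I-U designations).
#'
#' @param records catalogued spacer records.
#' @param hits row-bound hit tables (perfect hits are counted).
#' @param metadata strain metadata with `species`.
#' @return data.frame with columns `grouping`, `group`, `n_spacers`,
#'   `n_prophage`, `pct_prophage`, `n_known_mge`, `pct_known_mge`.
#' @export
match_summary <- function(records, hits, metadata = NULL) {
  hits <- hits[hits$category == "perfect", , drop = FALSE]
  hit_classes <- split(hits$target_class, hits$spacer_id)
  rec <- records
  rec$hits_prophage <- vapply(rec$spacer_id, function(id) {
    "prophage" %in% (hit_classes[[id]] %||% character(0))
  }, TRUE)
  rec$hits_mge <- vapply(rec$spacer_id, function(id) {
    "known_MGE" %in% (hit_classes[[id]] %||% character(0))
  }, TRUE)
  if (!is.null(metadata)) {
    rec$species <- metadata$species[match(rec$strain_id, metadata$strain_id)]
  }
  rec$cas_group <- ifelse(rec$cas_associated, "cas_associated", "cas_devoid")
  rec$family_group <- subtype_family(rec$subtype_context)

  one <- function(grouping, key) {
    sub <- rec[!is.na(rec[[key]]), , drop = FALSE]
    rows <- lapply(split(sub, sub[[key]]), function(g) {
      # distinct canonicals within the group; a canonical matches if any of
      # its records does
      agg_p <- vapply(split(g$hits_prophage, g$canonical), any, TRUE)
      agg_m <- vapply(split(g$hits_mge, g$canonical), any, TRUE)
      n <- length(agg_p)
      data.frame(grouping = grouping, group = g[[key]][1L], n_spacers = n,
                 n_prophage = sum(agg_p),
                 pct_prophage = round(100 * sum(agg_p) / max(1L, n), 1),
                 n_known_mge = sum(agg_m),
                 pct_known_mge = round(100 * sum(agg_m) / max(1L, n), 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one("strain", "strain_id"),
               if (!is.null(metadata)) one("species", "species"),
               one("cas", "cas_group"),
               one("subtype_family", "family_group"))
  rownames(out) <- NULL
  out
}

#' Positions of matching spacers within arrays (encounter history)
#'
#' For spacers hitting any target of one family, reports their positions
#' within each array ordered trailer to leader, with a span statistic
#' (max - min trailer index). Matches confined to the two leader-most
#' positions are flagged `recent_only`; matches spread across the array
#' indicate recurring encounters with that element family over time.
#'
#' @param records spacer records.
#' @param hits hit table.
#' @param targets target table with `region_id` and `family` (used to filter
#'   hits to one family); NULL to use all hits.
#' @param family family label to restrict to (requires `targets`).
#' @return list with `positions` (per matched spacer: locus, trailer/leader
#'   index, category) and `summary` (per locus: `n_matched`, `span`,
#'   `recent_only`).
#' @export
encounter_history <- function(records, hits, targets = NULL, family = NULL) {
  if (!is.null(family)) {
    stopifnot(!is.null(targets))
    ids <- targets$region_id[!is.na(targets$family) & targets$family == family]
    hits <- hits[hits$target_id %in% ids, , drop = FALSE]
  }
  m <- merge(records, unique(hits[, c("spacer_id", "category")]), by = "spacer_id")
  if (nrow(m) == 0L) {
    return(list(positions = data.frame(locus_id = character(0), spacer_id = character(0),
                                       index_from_trailer = integer(0),
                                       index_from_leader = integer(0),
                                       category = character(0), stringsAsFactors = FALSE),
                summary = data.frame(locus_id = character(0), n_spacers = integer(0),
                                     n_matched = integer(0), span = integer(0),
                                     recent_only = logical(0), stringsAsFactors = FALSE)))
  }
  # a spacer with both perfect and partial hits counts as perfect
  m$rank <- ifelse(m$category == "perfect", 1L, 2L)
  m <- m[order(m$spacer_id, m$rank), , drop = FALSE]
  m <- m[!duplicated(m$spacer_id), , drop = FALSE]
  positions <- m[order(m$locus_id, m$index_from_trailer),
                 c("locus_id", "spacer_id", "index_from_trailer",
                   "index_from_leader", "category")]
  rownames(positions) <- NULL
  n_per_locus <- vapply(split(records$spacer_id, records$locus_id), length, 0L)
  summ <- do.call(rbind, lapply(split(positions, positions$locus_id), function(g) {
    n_sp <- n_per_locus[[g$locus_id[1L]]]
    span <- max(g$index_from_trailer) - min(g$index_from_trailer)
    leader_idx <- g$index_from_leader
    recent <- if (all(!is.na(leader_idx))) {
      span <= 1L && all(leader_idx <= 1L)
    } else {
      span <= 1L && all(g$index_from_trailer >= n_sp - 2L)
    }
    data.frame(locus_id = g$locus_id[1L], n_spacers = n_sp, n_matched = nrow(g),
               span = span, recent_only = recent, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(positions = positions, summary = summ)
}
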