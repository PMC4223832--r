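#' Extract spacer records from detected loci
#'
#' One record per spacer interval. Indices are assigned from the trailer end
#' (0 = most ancestral spacer); leader-relative indices are defined only when
#' the locus orientation is known. For a `leader_right` locus the leftmost
#' spacer is the trailer; for `leader_left` the rightmost is.
#'
#' @param loci list of `crispr_locus` (typically confirmed only).
#' @return data.frame with columns `spacer_id`, `strain_id`, `locus_id`,
#'   `sequence`, `canonical`, `length`, `index_from_trailer`,
#'   `index_from_leader`, `cas_associated`, `subtype_context`.
#' @export
extract_spacers <- function(loci) {
  rows <- lapply(loci, function(l) {
    ns <- length(l$spacer_starts)
    if (ns == 0L) return(NULL)
    # genomic left-to-right positions 0..ns-1
    pos <- seq_len(ns) - 1L
    if (l$orientation == "leader_left") {
      idx_trailer <- ns - 1L - pos
      idx_leader <- pos
    } else {
      # leader_right or unknown: count trailer from the left
      idx_trailer <- pos
      idx_leader <- if (l$orientation == "leader_right") ns - 1L - pos else NA_integer_
    }
    data.frame(
      spacer_id = paste(l$locus_id, idx_trailer, sep = "|"),
      strain_id = l$strain_id,
      locus_id = l$locus_id,
      sequence = l$spacers,
      canonical = canonical_spacer(l$spacers),
      length = nchar(l$spacers),
      index_from_trailer = idx_trailer,
      index_from_leader = idx_leader,
      cas_associated = l$cas_associated,
      subtype_context = l$subtype_context,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(spacer_id = character(0), strain_id = character(0),
                      locus_id = character(0), sequence = character(0),
                      canonical = character(0), length = integer(0),
                      index_from_trailer = integer(0), index_from_leader = integer(0),
                      cas_associated = logical(0), subtype_context = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build the cross-strain spacer catalog
#'
#' Spacers are clustered by exact canonical (strand-folded) identity. A
#' distinct canonical is "shared" iff it occurs in at least two distinct
#' strains; repeats within one strain count once towards sharing. Spacer
#' sequences containing N (e.g. the assembly-gap pseudo-spacers of merged
#' loci) are excluded from the catalog. Raw-strand counts (exact string
#' identity without strand folding) are reported alongside for comparison.
#'
#' @param records spacer records from [extract_spacers()] (any number of
#'   strains, row-bound).
#' @return list with `records` (the catalogued records), `table` (one row
#'   per canonical: `canonical`, `length`, `n_records`, `n_strains`,
#'   `strains`, `shared`), `unique_count`, `shared_count`,
#'   `raw_unique_count`, `raw_shared_count`.
#' @export
build_catalog <- function(records) {
  records <- records[!grepl("N", records$sequence, fixed = TRUE), , drop = FALSE]
  sp <- split(records, records$canonical)
  tab <- do.call(rbind, lapply(sp, function(g) data.frame(
    canonical = g$canonical[1L],
    length = nchar(g$canonical[1L]),
    n_records = nrow(g),
    n_strains = length(unique(g$strain_id)),
    strains = paste(sort(unique(g$strain_id)), collapse = ","),
    stringsAsFactors = FALSE)))
  if (is.null(tab)) {
    tab <- data.frame(canonical = character(0), length = integer(0),
                      n_records = integer(0), n_strains = integer(0),
                      strains = character(0), shared = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    tab$shared <- tab$n_strains >= 2L
    tab <- tab[order(tab$canonical), , drop = FALSE]
    rownames(tab) <- NULL
  }
  raw <- vapply(split(records$strain_id, records$sequence),
                function(s) length(unique(s)), 0L)
  structure(list(
    records = records,
    table = tab,
    unique_count = sum(!tab$shared),
    shared_count = sum(tab$shared),
    raw_unique_count = sum(raw < 2L),
    raw_shared_count = sum(raw >= 2L)
  ), class = "spacer_catalog")
}

#' Per-strain CRISPR summary table
#'
#' Loci counts (with per-Mb normalization to 0.1), spacer counts and
#' mean +/- SD spacers per locus, the fraction of loci with an associated
#' cas cluster, and the subtype inventory. Confirmed loci only.
#'
#' @param catalog a `spacer_catalog`.
#' @param loci list of `crispr_locus` (confirmed).
#' @param clusters list of classified `cas_cluster`.
#' @param genomes named list of `genome_record`.
#' @return data.frame, one row per strain.
#' @export
per_strain_summary <- function(catalog, loci, clusters, genomes) {
  rows <- lapply(names(genomes), function(sid) {
    g <- genomes[[sid]]
    sl <- Filter(function(l) l$strain_id == sid, loci)
    n_loci <- length(sl)
    spacers_per_locus <- vapply(sl, function(l) length(l$spacer_starts), 0L)
    n_spacers <- sum(spacers_per_locus)
    n_assoc <- sum(vapply(sl, function(l) isTRUE(l$cas_associated), TRUE))
    subs <- sort(unique(stats::na.omit(vapply(clusters, function(cl) {
      if (cl$strain_id == sid) cl$subtype else NA_character_
    }, ""))))
    data.frame(
      strain_id = sid,
      genome_size = g$genome_size,
      n_loci = n_loci,
      loci_per_mb = round(n_loci / (g$genome_size / 1e6), 1),
      n_spacers = n_spacers,
      spacers_per_locus_mean = if (n_loci) round(mean(spacers_per_locus), 1) else NA_real_,
      spacers_per_locus_sd = if (n_loci > 1L) round(stats::sd(spacers_per_locus), 1) else NA_real_,
      locus_size_mean = if (n_loci) round(mean(vapply(sl, function(l) l$end - l$start, 0L)), 0) else NA_real_,
      pct_loci_cas = if (n_loci) round(100 * n_assoc / n_loci, 1) else 0,
      subtypes = paste(subs, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species summary table
#'
#' Aggregates the per-strain table to species rows: genomes analysed, total
#' and per-strain (per-Mb) locus counts, mean locus size, percentage of loci
#' with cas arrays, spacer totals and means, prophages per strain, and the
#' percentage of distinct spacers with perfect prophage / known-MGE matches.
#'
#' @param per_strain output of [per_strain_summary()].
#' @param metadata strain metadata with `species`.
#' @param match_summary optional output of [match_summary()] grouped by
#'   species (rows with `grouping == "species"`).
#' @param prophages optional prophage region table (with `strain_id`).
#' @return data.frame, one row per species.
#' @export
species_summary <- function(per_strain, metadata, match_summary = NULL,
                            prophages = NULL) {
  df <- merge(per_strain, metadata[, c("strain_id", "species")], by = "strain_id")
  rows <- lapply(split(df, df$species), function(g) {
    out <- data.frame(
      species = g$species[1L],
      n_genomes = nrow(g),
      total_crisprs = sum(g$n_loci),
      loci_per_strain = round(mean(g$n_loci), 1),
      loci_per_mb = round(mean(g$loci_per_mb), 1),
      locus_size_mean = round(mean(g$locus_size_mean, na.rm = TRUE), 0),
      pct_loci_cas = round(mean(g$pct_loci_cas), 1),
      total_spacers = sum(g$n_spacers),
      spacers_per_strain_mean = round(mean(g$n_spacers), 1),
      spacers_per_strain_sd = if (nrow(g) > 1L) round(stats::sd(g$n_spacers), 1) else NA_real_,
      prophages_per_strain = NA_real_,
      pct_spacers_prophage = NA_real_,
      pct_spacers_mge = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(prophages)) {
      n <- sum(prophages$strain_id %in% g$strain_id, na.rm = TRUE)
      out$prophages_per_strain <- round(n / nrow(g), 1)
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(match_summary)) {
    ms <- match_summary[match_summary$grouping == "species", , drop = FALSE]
    idx <- match(out$species, ms$group)
    out$pct_spacers_prophage <- ms$pct_prophage[idx]
    out$pct_spacers_mge <- ms$pct_known_mge[idx]
  }
  rownames(out) <- NULL
  out
}
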