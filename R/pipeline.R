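#' Run the full CRISPR-Cas comparative pipeline
#'
#' Orchestrates all stages: array detection and N-gap merging per strain,
#' confirmed-only filtering, cas cluster detection and subtype
#' classification from annotations, locus-cas association and orientation,
#' paired-locus detection, spacer extraction and cataloguing, perfect
#' matching against prophages and the known-MGE database (plus partial
#' matching against the latter), per-strain self-targeting scans,
#' match summaries, per-strain and per-species tables, homologous-locus
#' alignment with optional group-specific blocks, SNP spacer variants,
#' location-restricted sharing, and the statistical battery.
#'
#' @param genomes a `crispr_simulation`, or a named list of `genome_record`
#'   objects.
#' @param metadata strain metadata data.frame (ignored when `genomes` is a
#'   simulation).
#' @param annotations named list (by strain) of annotation data.frames.
#' @param prophages prophage region table ([read_regions()]).
#' @param mge_db known-MGE region table.
#' @param det_cfg a [detection_config()].
#' @param signatures subtype signature table.
#' @param assoc_distance locus-cas association distance (nt).
#' @param self_margin exclusion margin around loci in the self scan (nt).
#' @param groups optional named list of strain groups for block detection
#'   (e.g. subclades).
#' @param out_dir optional report directory ([write_report()]).
#' @return a result list (loci, tables, catalog, hits, summaries,
#'   alignment/blocks/variants, sharing, stats).
#' @export
run_pipeline <- function(genomes, metadata = NULL, annotations = NULL,
                         prophages = NULL, mge_db = NULL,
                         det_cfg = detection_config(),
                         signatures = default_subtype_signatures(),
                         assoc_distance = 1000L, self_margin = 100L,
                         groups = NULL, out_dir = NULL) {
  if (inherits(genomes, "crispr_simulation")) {
    sim <- genomes
    genomes <- sim$genomes
    metadata <- sim$metadata
    annotations <- sim$annotations
    prophages <- sim$prophages
    mge_db <- sim$mge_db
  }
  stopifnot(is.list(genomes), !is.null(metadata))

  ## detection + merging
  loci <- list()
  for (sid in names(genomes)) {
    g <- genomes[[sid]]
    found <- find_candidate_arrays(g, det_cfg)
    for (ctg in names(g$contigs)) {
      on_ctg <- Filter(function(l) l$contig_id == ctg, found)
      merged <- merge_adjacent_loci(on_ctg, g$contigs[[ctg]], det_cfg)
      loci <- c(loci, merged)
    }
  }

  ## cas clusters
  clusters <- list()
  for (sid in names(genomes)) {
    ann <- annotations[[sid]]
    if (is.null(ann) || nrow(ann) == 0L) next
    cls <- find_cas_clusters(ann, sid)
    cls <- lapply(cls, classify_subtype, signatures = signatures)
    clusters <- c(clusters, cls)
  }

  ## association + orientation
  assoc <- associate_crispr_cas(loci, clusters, max_distance = assoc_distance)
  loci <- assoc$loci
  cl_by_id <- stats::setNames(clusters, vapply(clusters, function(c) c$cluster_id, ""))
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    if (isTRUE(l$cas_associated)) {
      cl <- cl_by_id[[l$cluster_id]]
      side <- if (cl$start >= l$end) "right" else "left"
      loci[[i]] <- orient_locus(l, cas_side = side)
    } else {
      loci[[i]] <- orient_locus(l)
    }
  }
  pairs <- detect_paired_loci(loci, clusters, max_distance = assoc_distance)

  ## catalog (confirmed loci only)
  confirmed <- Filter(function(l) l$confidence == "confirmed", loci)
  records <- extract_spacers(confirmed)
  catalog <- build_catalog(records)

  ## matching
  hits <- empty_hits()
  if (!is.null(prophages) && nrow(prophages) > 0L && nrow(catalog$records) > 0L) {
    hits <- rbind(hits, perfect_match(catalog$records, prophages))
  }
  if (!is.null(mge_db) && nrow(mge_db) > 0L && nrow(catalog$records) > 0L) {
    hits <- rbind(hits, perfect_match(catalog$records, mge_db))
    hits <- rbind(hits, partial_match(catalog$records, mge_db))
  }
  self_hits <- do.call(rbind, c(list(cbind(empty_hits(),
                                           overlaps_prophage = logical(0),
                                           in_crispr_locus = logical(0))),
    lapply(names(genomes), function(sid) {
      self_targeting_scan(genomes[[sid]],
                          Filter(function(l) l$strain_id == sid, confirmed),
                          catalog$records, prophages, margin = self_margin)
    })))

  ## summaries
  msum <- match_summary(catalog$records, hits, metadata)
  per_strain <- per_strain_summary(catalog, confirmed, clusters, genomes)
  sp_sum <- if ("species" %in% names(metadata)) {
    species_summary(per_strain, metadata, msum, prophages)
  } else NULL

  ## encounter history for the SV1-like prophage family, when present
  history <- NULL
  if (!is.null(prophages) && any(prophages$family == "SV1", na.rm = TRUE)) {
    history <- encounter_history(catalog$records, hits, targets = prophages,
                                 family = "SV1")
  }

  ## array comparison
  homologous <- find_homologous_loci(confirmed, catalog$records)
  alignment <- NULL
  blocks <- NULL
  if (!is.null(groups)) {
    wanted <- sort(unique(unlist(groups)))
    lid_strain <- stats::setNames(vapply(confirmed, function(l) l$strain_id, ""),
                                  vapply(confirmed, function(l) l$locus_id, ""))
    cand <- Filter(function(g) all(wanted %in% lid_strain[g]), homologous)
    if (length(cand) > 0L) {
      # prefer the group whose per-strain arrays share the largest common
      # token backbone (one locus per strain)
      pick <- function(g) {
        g <- g[lid_strain[g] %in% wanted]
        g[!duplicated(lid_strain[g])]
      }
      backbone_size <- vapply(cand, function(g) {
        toks <- lapply(pick(g), function(id) {
          unique(catalog$records$canonical[catalog$records$locus_id == id])
        })
        length(Reduce(intersect, toks))
      }, 0L)
      grp <- pick(cand[[which.max(backbone_size)]])
      sel <- Filter(function(l) l$locus_id %in% grp, confirmed)
      arrays <- token_arrays(sel, catalog$records)
      alignment <- align_token_arrays(arrays)
      blocks <- group_specific_blocks(alignment, groups)
    }
  }
  variants <- if ("location" %in% names(metadata)) {
    find_spacer_variants(catalog, metadata)
  } else NULL

  ## biogeography + statistics
  sharing <- if (all(c("location", "biome") %in% names(metadata))) {
    location_restricted_fraction(catalog, metadata)
  } else list(fraction = NA_real_, table = data.frame())
  stats_tab <- run_stat_battery(per_strain, metadata, prophages,
                                msum[msum$grouping == "strain", , drop = FALSE])

  results <- list(
    genomes = genomes, metadata = metadata,
    loci = loci, loci_table = loci_table(loci),
    clusters = clusters, clusters_table = clusters_table(clusters),
    pairs = pairs,
    records = records, catalog = catalog,
    hits = hits, self_hits = self_hits,
    match_summary = msum,
    per_strain = per_strain, species_summary = sp_sum,
    history = history,
    homologous = homologous, alignment = alignment, blocks = blocks,
    variants = variants,
    sharing = sharing, stats = stats_tab
  )
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}
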