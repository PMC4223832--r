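#' Cas gene-name normalization
#'
#' Case-insensitive normalization with an alias table covering common
#' annotation dialects (cse1 = cas8e, cas8c = csd1, cst1-like variants).
#'
#' @param x character vector of gene names.
#' @param aliases named character vector mapping alias -> canonical name.
#' @return normalized names (lowercase canonical vocabulary).
#' @export
normalize_gene_name <- function(x, aliases = default_gene_aliases()) {
  v <- tolower(trimws(x))
  v <- gsub("_", "-", v)
  hit <- v %in% names(aliases)
  v[hit] <- unname(aliases[v[hit]])
  v
}

#' @rdname normalize_gene_name
#' @export
default_gene_aliases <- function() {
  c("cas8e" = "cse1", "casa" = "cse1", "casb" = "cse2",
    "csd1" = "cas8c", "cst1" = "cst1-like", "cst1like" = "cst1-like")
}

#' @rdname normalize_gene_name
#' @export
cas_gene_vocabulary <- function() {
  c(paste0("cas", 1:10), "cse1", "cse2", "cas8a", "cas8b", "cas8c",
    "cst1-like", "csb1", "csb2", "csb3", "csx17",
    paste0("csy", 1:4), paste0("cmr", 1:6), "csn1", "csn2")
}

#' Subtype signature table
#'
#' Set-based signatures for the six type I subtypes observed in Salinispora:
#' the three canonical subtypes (I-E, I-C, I-B, with cas8b replaced by a
#' larger cst1-related gene in I-B) and the three I-U designations built
#' around csb3, csx17 and the csb1/csb2 pair, of which I-U_csx17 and I-U_Sa
#' lack cas1. Classification picks the highest-priority signature whose
#' required set is contained in the cluster and whose forbidden set is
#' disjoint from it; any cluster lacking cas3 (the type I signature gene)
#' stays unclassified. The table is a reconstruction from subtype names and
#' the canonical type I gene vocabulary and can be replaced via YAML
#' ([signatures_from_yaml()]).
#'
#' @return list of signature lists with `subtype`, `required`, `optional`,
#'   `forbidden`, `priority`.
#' @export
default_subtype_signatures <- function() {
  list(
    list(subtype = "I-E", required = c("cas3", "cse1", "cse2"),
         optional = c("cas7", "cas5", "cas6", "cas1", "cas2"),
         forbidden = character(0), priority = 1L),
    list(subtype = "I-C", required = c("cas3", "cas8c"),
         optional = c("cas7", "cas5", "cas4", "cas1", "cas2"),
         forbidden = character(0), priority = 2L),
    list(subtype = "I-B", required = c("cas3", "cst1-like"),
         optional = c("cas7", "cas5", "cas6", "cas4", "cas1", "cas2"),
         forbidden = character(0), priority = 3L),
    list(subtype = "I-U_csb3", required = c("cas3", "csb3"),
         optional = c("csb1", "csb2", "cas1", "cas2"),
         forbidden = character(0), priority = 4L),
    list(subtype = "I-U_csx17", required = c("cas3", "csx17"),
         optional = c("csb1", "csb2"),
         forbidden = "cas1", priority = 5L),
    list(subtype = "I-U_Sa", required = c("cas3", "csb1", "csb2"),
         optional = character(0),
         forbidden = c("csb3", "csx17", "cas1"), priority = 6L)
  )
}

#' @rdname default_subtype_signatures
#' @param path YAML file: a list of entries with fields `subtype`,
#'   `required`, `optional`, `forbidden`, `priority`.
#' @export
signatures_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    list(subtype = e$subtype,
         required = as.character(e$required %||% character(0)),
         optional = as.character(e$optional %||% character(0)),
         forbidden = as.character(e$forbidden %||% character(0)),
         priority = as.integer(e$priority))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find cas gene clusters
#'
#' Maximal runs of cas-vocabulary genes on one contig with intergenic gaps
#' at most `max_intergenic_gap`; an interleaved non-cas gene splits a run.
#'
#' @param genes annotation data.frame (see [read_annotations()]).
#' @param strain_id strain the genes belong to.
#' @param max_intergenic_gap maximum gap between consecutive cas genes (nt).
#' @param aliases alias table for [normalize_gene_name()].
#' @return list of `cas_cluster` objects (fields `cluster_id`, `strain_id`,
#'   `contig_id`, `start`, `end`, `genes` data.frame, `gene_names`,
#'   `has_cas1`, `has_cas3`).
#' @export
find_cas_clusters <- function(genes, strain_id, max_intergenic_gap = 500L,
                              aliases = default_gene_aliases()) {
  if (nrow(genes) == 0L) return(list())
  genes$norm_name <- normalize_gene_name(genes$name, aliases)
  genes$is_cas <- genes$norm_name %in% cas_gene_vocabulary()
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  clusters <- list()
  for (ctg in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == ctg, , drop = FALSE]
    cas <- g[g$is_cas, , drop = FALSE]
    if (nrow(cas) == 0L) next
    brk <- logical(nrow(cas))
    if (nrow(cas) > 1L) {
      for (i in 2:nrow(cas)) {
        gap <- cas$start[i] - cas$end[i - 1L]
        interleaved <- any(!g$is_cas & g$start >= cas$end[i - 1L] & g$end <= cas$start[i])
        brk[i] <- gap > max_intergenic_gap || interleaved
      }
    }
    grp <- cumsum(brk)
    for (k in unique(grp)) {
      sub <- cas[grp == k, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- structure(list(
        cluster_id = NA_character_,
        strain_id = strain_id,
        contig_id = ctg,
        start = min(sub$start),
        end = max(sub$end),
        genes = sub[, c("contig_id", "start", "end", "strand", "name", "norm_name")],
        gene_names = sub$norm_name,
        subtype = NA_character_,
        complete = NA,
        has_cas1 = "cas1" %in% sub$norm_name,
        has_cas3 = "cas3" %in% sub$norm_name
      ), class = "cas_cluster")
    }
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$cluster_id <- paste0(strain_id, "|cas", i)
  }
  clusters
}

#' Classify a cas cluster into a subtype
#'
#' Applies the signature table (set-based, permutation-invariant to gene
#' order): the highest-priority signature whose required genes are all
#' present and whose forbidden genes are all absent wins. Clusters lacking
#' cas3 are always `unclassified`. Completeness additionally requires cas1
#' and cas2, except for subtypes whose definition forbids cas1.
#'
#' @param cluster a `cas_cluster`.
#' @param signatures signature table (see [default_subtype_signatures()]).
#' @return the cluster with `subtype` and `complete` set.
#' @export
classify_subtype <- function(cluster, signatures = default_subtype_signatures()) {
  genes <- unique(cluster$gene_names)
  cluster$subtype <- "unclassified"
  cluster$complete <- FALSE
  if (!cluster$has_cas3) return(cluster)
  ord <- order(vapply(signatures, function(s) s$priority, 0L))
  for (s in signatures[ord]) {
    if (all(s$required %in% genes) && !any(s$forbidden %in% genes)) {
      cluster$subtype <- s$subtype
      cluster$complete <- if ("cas1" %in% s$forbidden) {
        TRUE
      } else {
        all(c("cas1", "cas2") %in% genes)
      }
      break
    }
  }
  cluster
}

#' Associate CRISPR loci with cas clusters
#'
#' Each locus is associated with the nearest cluster on the same contig
#' within `max_distance` edge-to-edge; both members of a paired locus
#' associate with the internal cluster. Sets `cas_associated`, `cluster_id`
#' and `subtype_context` on the loci.
#'
#' @param loci list of `crispr_locus`.
#' @param clusters list of classified `cas_cluster` objects.
#' @param max_distance maximum edge-to-edge distance (nt).
#' @return list with `loci` (updated) and `map` (data.frame locus_id,
#'   cluster_id, distance).
#' @export
associate_crispr_cas <- function(loci, clusters, max_distance = 1000L) {
  map <- data.frame(locus_id = character(0), cluster_id = character(0),
                    distance = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    best <- NULL; best_d <- Inf
    for (cl in clusters) {
      if (cl$strain_id != l$strain_id || cl$contig_id != l$contig_id) next
      d <- if (cl$start >= l$end) cl$start - l$end
           else if (l$start >= cl$end) l$start - cl$end
           else 0L
      if (d <= max_distance && d < best_d) { best <- cl; best_d <- d }
    }
    if (!is.null(best)) {
      loci[[i]]$cas_associated <- TRUE
      loci[[i]]$cluster_id <- best$cluster_id
      loci[[i]]$subtype_context <- best$subtype
      map <- rbind(map, data.frame(locus_id = l$locus_id, cluster_id = best$cluster_id,
                                   distance = as.integer(best_d), stringsAsFactors = FALSE))
    }
  }
  list(loci = loci, map = map)
}

#' GC contrast between a region and its genome
#'
#' GC = (G+C)/(A+C+G+T) with N excluded from the denominator; percentages
#' reported to 0.1. Used to contrast horizontally acquired cas arrays (e.g.
#' I-C) against the genomic background.
#'
#' @param genome a `genome_record`.
#' @param contig_id contig holding the region.
#' @param start,end region interval, 0-based half-open.
#' @return list with `region_gc`, `genome_gc`, `difference` (percentage
#'   points).
#' @export
gc_contrast <- function(genome, contig_id, start, end) {
  if (end <= start) stop("empty region")
  seq <- genome$contigs[[contig_id]]
  if (is.null(seq) || end > nchar(seq)) stop("region outside contig")
  region_gc <- round(100 * gc_fraction(subseq0(seq, start, end)), 1)
  genome_gc <- round(100 * gc_fraction(paste(genome$contigs, collapse = "")), 1)
  list(region_gc = region_gc, genome_gc = genome_gc,
       difference = round(region_gc - genome_gc, 1))
}

#' Tabulate cas clusters
#'
#' @param clusters list of `cas_cluster` objects.
#' @return one row per cluster.
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(cluster_id = character(0), strain_id = character(0),
                      contig_id = character(0), start = integer(0), end = integer(0),
                      subtype = character(0), n_genes = integer(0),
                      genes = character(0), complete = logical(0),
                      has_cas1 = logical(0), has_cas3 = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, strain_id = cl$strain_id, contig_id = cl$contig_id,
    start = cl$start, end = cl$end, subtype = cl$subtype,
    n_genes = length(cl$gene_names),
    genes = paste(cl$gene_names, collapse = ","),
    complete = cl$complete, has_cas1 = cl$has_cas1, has_cas3 = cl$has_cas3,
    stringsAsFactors = FALSE)))
  df <- df[order(df$strain_id, df$contig_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
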