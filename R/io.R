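#' Read strain genomes and metadata
#'
#' Loads one FASTA per strain together with a strain metadata table. Sequences
#' are uppercased; any symbol outside A/C/G/T/N is rejected. Every strain in
#' the metadata must have a genome file, and contig ids must be unique.
#'
#' @param genomes either a directory containing `<strain_id>.fasta` files, or
#'   a character vector of FASTA paths named by strain id (unnamed paths use
#'   the file base name as strain id).
#' @param metadata path to a tab-separated metadata table with at least a
#'   `strain_id` column (optional: `species`, `phylotype`, `location`,
#'   `biome`, `latitude`, `longitude`, `depth`, `date`, `gene_count`), or an
#'   equivalent `data.frame`.
#' @return a list with `genomes` (named list of `genome_record` objects, each
#'   holding `strain_id`, `contigs` (named character), `genome_size`,
#'   `gene_count`) and `metadata` (data.frame).
#' @export
read_genomes <- function(genomes, metadata) {
  md <- if (is.data.frame(metadata)) metadata else read_strain_metadata(metadata)
  if (!"strain_id" %in% names(md)) stop("metadata must contain a strain_id column")
  if (anyDuplicated(md$strain_id)) stop("duplicate strain_id in metadata")

  if (length(genomes) == 1L && dir.exists(genomes)) {
    files <- list.files(genomes, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    names(files) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
    genomes <- files
  }
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    names(genomes) <- sub("\\.(fa|fasta|fna)$", "", basename(genomes))
  }

  missing <- setdiff(md$strain_id, names(genomes))
  if (length(missing) > 0L) {
    stop("no genome FASTA for strain(s): ", paste(missing, collapse = ", "))
  }

  out <- lapply(md$strain_id, function(sid) {
    path <- genomes[[sid]]
    if (!file.exists(path)) stop("genome file missing for strain ", sid, ": ", path)
    ss <- Biostrings::readDNAStringSet(path)
    contigs <- toupper(as.character(ss))
    names(contigs) <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(names(contigs))) {
      stop("duplicate contig id in genome of strain ", sid)
    }
    bad <- grepl("[^ACGTN]", contigs)
    if (any(bad)) {
      stop("strain ", sid, ": contig ", names(contigs)[bad][1L],
           " contains symbols outside A/C/G/T/N")
    }
    gene_count <- if ("gene_count" %in% names(md)) {
      md$gene_count[md$strain_id == sid]
    } else NA_integer_
    genome_record(sid, contigs, gene_count)
  })
  names(out) <- md$strain_id
  list(genomes = out, metadata = md)
}

#' @rdname read_genomes
#' @param strain_id strain identifier.
#' @param contigs named character vector of contig sequences.
#' @param gene_count number of annotated genes (optional).
#' @export
genome_record <- function(strain_id, contigs, gene_count = NA_integer_) {
  contigs <- toupper(contigs)
  stopifnot(!is.null(names(contigs)), !anyDuplicated(names(contigs)))
  if (any(grepl("[^ACGTN]", contigs))) stop("sequences must contain only A/C/G/T/N")
  structure(list(strain_id = strain_id,
                 contigs = contigs,
                 genome_size = sum(nchar(contigs)),
                 gene_count = as.integer(gene_count)),
            class = "genome_record")
}

#' Read the strain metadata table
#'
#' @param path tab-separated file with a header row.
#' @return data.frame.
#' @export
read_strain_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read gene annotations (GFF3 or gene TSV)
#'
#' GFF3 coordinates (1-based closed) are converted to the package-internal
#' 0-based half-open convention. Records whose end precedes their start are
#' dropped with a warning; the count of dropped records is attached as the
#' `n_rejected` attribute.
#'
#' @param path GFF3 file (`.gff`/`.gff3`) or tab-separated gene table with
#'   columns `contig_id`, `start`, `end` (1-based closed), `strand`, `name`,
#'   `product`.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `product`.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    ok9 <- vapply(fields, length, 1L) == 9L
    starts <- suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[4] else NA_character_, "")))
    ends <- suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")))
    valid <- ok9 & !is.na(starts) & !is.na(ends) & ends >= starts
    n_rejected <- sum(!valid)
    if (n_rejected > 0L) {
      warning(n_rejected, " annotation record(s) rejected (end < start or malformed)")
    }
    tmp <- tempfile(fileext = ".gff3")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c("##gff-version 3", body[valid]), tmp)
    gr <- rtracklayer::import(tmp, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    name <- if ("Name" %in% names(mc)) as.character(mc$Name) else rep(NA_character_, length(gr))
    if ("gene" %in% names(mc)) {
      name <- ifelse(is.na(name), as.character(mc$gene), name)
    }
    product <- if ("product" %in% names(mc)) as.character(mc$product) else rep(NA_character_, length(gr))
    out <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      name = name,
      product = product,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    valid <- !is.na(df$start) & !is.na(df$end) & df$end >= df$start
    n_rejected <- sum(!valid)
    if (n_rejected > 0L) {
      warning(n_rejected, " annotation record(s) rejected (end < start)")
    }
    df <- df[valid, , drop = FALSE]
    out <- data.frame(
      contig_id = df$contig_id,
      start = as.integer(df$start) - 1L,
      end = as.integer(df$end),
      strand = ifelse(df$strand == "-", "-", "+"),
      name = df$name,
      product = if ("product" %in% names(df)) df$product else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

# Parse "key=value" tags from FASTA header lines.
parse_header_tags <- function(headers) {
  ids <- sub("\\s.*$", "", headers)
  tag <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^ ]+"), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(key, "="), headers)
    out[hit] <- sub(paste0("^", key, "="), "", regmatches(headers, regexpr(paste0(key, "=[^ ]+"), headers)))
    out
  }
  list(id = ids, class = tag("class"), family = tag("family"),
       strain = tag("strain"), intact = tag("intact"))
}

#' Read a region set (prophages or a known-MGE database)
#'
#' Regions are carried as sequences tagged in their FASTA headers
#' (`class=`, `family=`, `strain=`, `intact=`); an optional BED file
#' (0-based half-open) supplies on-chromosome coordinates for regions that
#' lie on strain contigs (BED name column = region id).
#'
#' @param fasta FASTA of region sequences with tagged headers.
#' @param bed optional BED file of on-contig intervals.
#' @param class_label default class for untagged records
#'   (`"prophage"`, `"known_MGE"` or `"island"`).
#' @return data.frame with columns `region_id`, `strain_id`, `contig_id`,
#'   `start`, `end`, `sequence`, `class`, `family`, `intact`.
#' @export
read_regions <- function(fasta, bed = NULL, class_label = "prophage") {
  ss <- Biostrings::readDNAStringSet(fasta)
  tags <- parse_header_tags(names(ss))
  out <- data.frame(
    region_id = tags$id,
    strain_id = tags$strain,
    contig_id = NA_character_,
    start = NA_integer_,
    end = NA_integer_,
    sequence = toupper(as.character(ss)),
    class = ifelse(is.na(tags$class), class_label, tags$class),
    family = tags$family,
    intact = ifelse(is.na(tags$intact), TRUE, tags$intact == "yes"),
    stringsAsFactors = FALSE
  )
  if (!is.null(bed)) {
    b <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
    names(b)[1:4] <- c("contig_id", "start", "end", "region_id")
    idx <- match(out$region_id, b$region_id)
    hit <- !is.na(idx)
    out$contig_id[hit] <- b$contig_id[idx[hit]]
    out$start[hit] <- as.integer(b$start[idx[hit]])
    out$end[hit] <- as.integer(b$end[idx[hit]])
  }
  if (any(!nzchar(out$sequence))) stop("empty region sequence in ", fasta)
  out
}

#' Write detected CRISPR loci as GFF3
#'
#' Each locus becomes a `repeat_region` parent feature with `direct_repeat`
#' and `spacer` children (`Parent` attributes). Internal 0-based half-open
#' coordinates are converted to GFF3 1-based closed ones; sequences are
#' carried in `seq` attributes so that a write/read round trip reproduces
#' both coordinates and sequences.
#'
#' @param loci list of `crispr_locus` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  if (length(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ord <- order(vapply(loci, function(l) l$strain_id, ""),
               vapply(loci, function(l) l$contig_id, ""),
               vapply(loci, function(l) l$start, 0))
  loci <- loci[ord]
  rows <- list()
  for (l in loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = l$contig_id, start = l$start + 1L, end = l$end,
      type = "repeat_region", ID = l$locus_id, Parent = NA_character_,
      strain_id = l$strain_id, seq = NA_character_,
      consensus = l$consensus, orientation = l$orientation,
      confidence = l$confidence, stringsAsFactors = FALSE)
    nr <- length(l$repeat_starts)
    for (i in seq_len(nr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = l$contig_id, start = l$repeat_starts[i] + 1L, end = l$repeat_ends[i],
        type = "direct_repeat", ID = paste0(l$locus_id, ".r", i), Parent = l$locus_id,
        strain_id = l$strain_id, seq = l$repeats[i],
        consensus = NA_character_, orientation = NA_character_,
        confidence = NA_character_, stringsAsFactors = FALSE)
    }
    for (i in seq_along(l$spacer_starts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = l$contig_id, start = l$spacer_starts[i] + 1L, end = l$spacer_ends[i],
        type = "spacer", ID = paste0(l$locus_id, ".s", i), Parent = l$locus_id,
        strain_id = l$strain_id, seq = l$spacers[i],
        consensus = NA_character_, orientation = NA_character_,
        confidence = NA_character_, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- df[, c("type", "ID", "Parent", "strain_id", "seq",
                                 "consensus", "orientation", "confidence")]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_loci_gff3
#' @export
read_loci_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(list())
  mc <- S4Vectors::mcols(gr)
  parents <- which(as.character(mc$type) == "repeat_region")
  parent_of <- vapply(mc$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  loci <- lapply(parents, function(i) {
    id <- as.character(mc$ID[i])
    kids <- which(parent_of == id)
    kt <- as.character(mc$type[kids])
    reps <- kids[kt == "direct_repeat"]
    spcs <- kids[kt == "spacer"]
    reps <- reps[order(GenomicRanges::start(gr)[reps])]
    spcs <- spcs[order(GenomicRanges::start(gr)[spcs])]
    structure(list(
      locus_id = id,
      strain_id = as.character(mc$strain_id[i]),
      contig_id = as.character(GenomicRanges::seqnames(gr)[i]),
      start = GenomicRanges::start(gr)[i] - 1L,
      end = GenomicRanges::end(gr)[i],
      repeat_starts = GenomicRanges::start(gr)[reps] - 1L,
      repeat_ends = GenomicRanges::end(gr)[reps],
      spacer_starts = GenomicRanges::start(gr)[spcs] - 1L,
      spacer_ends = GenomicRanges::end(gr)[spcs],
      repeats = as.character(mc$seq[reps]),
      spacers = as.character(mc$seq[spcs]),
      consensus = as.character(mc$consensus[i]),
      orientation = as.character(mc$orientation[i]),
      confidence = as.character(mc$confidence[i]),
      merged_from = character(0)
    ), class = "crispr_locus")
  })
  names(loci) <- vapply(loci, function(l) l$locus_id, "")
  loci
}

#' Write all pipeline outputs to a directory
#'
#' Emits the loci GFF3, the tabular outputs of every stage and a JSON summary
#' with deterministic ordering (strain, contig, start), so that reruns on the
#' same inputs are byte-identical.
#'
#' @param results a result list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_loci_gff3(results$loci, file.path(out_dir, "loci.gff3"))
  wtsv(results$loci_table, "loci.tsv")
  wtsv(results$clusters_table, "cas_clusters.tsv")
  wtsv(results$records, "spacers.tsv")
  wtsv(results$catalog$table, "spacer_catalog.tsv")
  wtsv(results$hits, "hits.tsv")
  wtsv(results$self_hits, "self_hits.tsv")
  wtsv(results$match_summary, "match_summary.tsv")
  wtsv(results$per_strain, "per_strain.tsv")
  wtsv(results$species_summary, "species_summary.tsv")
  wtsv(results$sharing$table, "sharing.tsv")
  wtsv(results$stats, "stats.tsv")
  json <- list(
    n_strains = length(results$genomes),
    n_loci = nrow(results$loci_table),
    n_confirmed_loci = sum(results$loci_table$confidence == "confirmed"),
    n_cas_clusters = nrow(results$clusters_table),
    n_spacers = nrow(results$records),
    distinct_spacers = results$catalog$unique_count + results$catalog$shared_count,
    unique_spacers = results$catalog$unique_count,
    shared_spacers = results$catalog$shared_count,
    pct_unique = round(100 * results$catalog$unique_count /
                         max(1L, results$catalog$unique_count + results$catalog$shared_count), 1),
    location_restricted_pct = results$sharing$fraction
  )
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(out_dir, "summary.json"))
  invisible(out_dir)
}
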