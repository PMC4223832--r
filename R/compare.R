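#' Group homologous loci across strains
#'
#' Loci are grouped when their consensus repeats are identical or exact
#' reverse complements AND the arrays share at least one canonical spacer
#' (transitively, within one consensus class). Singleton groups are allowed.
#'
#' @param loci list of `crispr_locus`.
#' @param records spacer records for those loci.
#' @return list of character vectors of locus ids (deterministic order).
#' @export
find_homologous_loci <- function(loci, records) {
  if (length(loci) == 0L) return(list())
  ids <- vapply(loci, function(l) l$locus_id, "")
  cons <- vapply(loci, function(l) l$consensus, "")
  canon_cons <- canonical_spacer(cons)  # strand-folded consensus key
  groups <- list()
  for (cc in sort(unique(canon_cons))) {
    members <- ids[canon_cons == cc]
    # union-find by shared canonical spacers
    parent <- stats::setNames(members, members)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    sp_by_locus <- lapply(members, function(id) {
      unique(records$canonical[records$locus_id == id])
    })
    names(sp_by_locus) <- members
    if (length(members) > 1L) {
      for (i in 1:(length(members) - 1L)) {
        for (j in (i + 1L):length(members)) {
          if (length(intersect(sp_by_locus[[i]], sp_by_locus[[j]])) > 0L) {
            ri <- find(members[i]); rj <- find(members[j])
            if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
          }
        }
      }
    }
    roots <- vapply(members, find, "")
    for (r in sort(unique(roots))) {
      groups[[length(groups) + 1L]] <- sort(members[roots == r])
    }
  }
  groups
}

#' Tokenized spacer arrays
#'
#' Represents each locus as the ordered list of its canonical spacer ids,
#' trailer end first. Loci with unknown orientation use the genomic
#' left-to-right order as trailer-to-leader.
#'
#' @param loci list of `crispr_locus`.
#' @param records spacer records for those loci.
#' @return named list (locus_id) of lists with `strain_id`, `locus_id`,
#'   `tokens`.
#' @export
token_arrays <- function(loci, records) {
  out <- lapply(loci, function(l) {
    r <- records[records$locus_id == l$locus_id, , drop = FALSE]
    r <- r[order(r$index_from_trailer), , drop = FALSE]
    list(strain_id = l$strain_id, locus_id = l$locus_id, tokens = r$canonical)
  })
  names(out) <- vapply(loci, function(l) l$locus_id, "")
  out
}

# Longest common subsequence of two token vectors: returns index pairs
# (ia, ib) of the aligned tokens. Standard dynamic program, deterministic
# traceback (prefers consuming from `a` on ties).
lcs_tokens <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(cbind(ia = integer(0), ib = integer(0)))
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    eq <- a[i] == b
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- if (eq[j]) d[i, j] + 1L else max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  ia <- integer(0); ib <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && d[i + 1L, j + 1L] == d[i, j] + 1L) {
      ia <- c(i, ia); ib <- c(j, ib); i <- i - 1L; j <- j - 1L
    } else if (d[i, j + 1L] >= d[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  cbind(ia = ia, ib = ib)
}

#' Align tokenized spacer arrays
#'
#' Pairwise alignment is the longest common subsequence over spacer tokens:
#' identical spacers align in one column, everything else gets gap columns
#' (no mismatch columns, mirroring the convention that vertically aligned
#' spacers are identical). More than two arrays are aligned progressively
#' against the growing profile, in descending array length (ties by strain
#' id, then locus id) for determinism. Unmatched tokens of a new array are
#' inserted as new columns immediately after the last matched column.
#'
#' @param arrays list of token arrays ([token_arrays()]), length >= 2.
#' @return list with `alignment` (matrix: rows = locus ids, columns =
#'   aligned positions, entries = token or NA), `strains` (row strain ids)
#'   and `shared_columns` (count of columns occupied by every array).
#' @export
align_token_arrays <- function(arrays) {
  stopifnot(length(arrays) >= 2L)
  lens <- vapply(arrays, function(a) length(a$tokens), 0L)
  sid <- vapply(arrays, function(a) a$strain_id, "")
  lid <- vapply(arrays, function(a) a$locus_id, "")
  ord <- order(-lens, sid, lid)
  arrays <- arrays[ord]
  # profile: list of columns, each a token value + occupancy per array index
  prof_tokens <- arrays[[1L]]$tokens
  occ <- matrix(TRUE, nrow = 1L, ncol = length(prof_tokens))
  for (ai in 2:length(arrays)) {
    tok <- arrays[[ai]]$tokens
    al <- lcs_tokens(prof_tokens, tok)
    ncol_new <- length(prof_tokens) + length(tok) - nrow(al)
    new_tokens <- character(0)
    new_occ <- matrix(FALSE, nrow = nrow(occ) + 1L, ncol = 0L)
    pi <- 1L; ti <- 1L
    push <- function(token, occ_col) {
      new_tokens[length(new_tokens) + 1L] <<- token
      new_occ <<- cbind(new_occ, occ_col)
    }
    for (k in seq_len(nrow(al) + 1L)) {
      pa <- if (k <= nrow(al)) al[k, "ia"] else length(prof_tokens) + 1L
      ta <- if (k <= nrow(al)) al[k, "ib"] else length(tok) + 1L
      while (pi < pa) {
        push(prof_tokens[pi], c(occ[, pi], FALSE))
        pi <- pi + 1L
      }
      while (ti < ta) {
        push(tok[ti], c(rep(FALSE, nrow(occ)), TRUE))
        ti <- ti + 1L
      }
      if (k <= nrow(al)) {
        push(prof_tokens[pa], c(occ[, pa], TRUE))
        pi <- pa + 1L; ti <- ta + 1L
      }
    }
    prof_tokens <- new_tokens
    occ <- new_occ
  }
  aln <- matrix(NA_character_, nrow = length(arrays), ncol = length(prof_tokens),
                dimnames = list(vapply(arrays, function(a) a$locus_id, ""), NULL))
  for (i in seq_along(arrays)) aln[i, occ[i, ]] <- prof_tokens[occ[i, ]]
  list(alignment = aln,
       strains = vapply(arrays, function(a) a$strain_id, ""),
       shared_columns = sum(colSums(occ) == nrow(occ)))
}

#' Group-specific spacer blocks in an alignment
#'
#' Maximal runs of consecutive alignment columns occupied by every member of
#' exactly one declared strain group and by no member of any other group.
#' Blocks are reported as insertion-or-deletion events without assigning a
#' direction (a block may have been deleted from the other lineages or
#' acquired by this one).
#'
#' @param aligned output of [align_token_arrays()].
#' @param groups named list: group label -> character vector of strain ids
#'   (every aligned strain in exactly one group).
#' @return data.frame with `block_id`, `group`, `start_col`, `end_col`,
#'   `length`, `tokens` (comma-joined).
#' @export
group_specific_blocks <- function(aligned, groups) {
  aln <- aligned$alignment
  strains <- aligned$strains
  stopifnot(all(strains %in% unlist(groups)))
  col_group <- vapply(seq_len(ncol(aln)), function(j) {
    present <- strains[!is.na(aln[, j])]
    for (gname in names(groups)) {
      g <- intersect(groups[[gname]], strains)
      if (length(present) > 0L && setequal(present, g)) return(gname)
    }
    NA_character_
  }, "")
  out <- data.frame(block_id = character(0), group = character(0),
                    start_col = integer(0), end_col = integer(0),
                    length = integer(0), tokens = character(0),
                    stringsAsFactors = FALSE)
  j <- 1L; bid <- 0L
  while (j <= length(col_group)) {
    if (!is.na(col_group[j])) {
      k <- j
      while (k < length(col_group) && !is.na(col_group[k + 1L]) &&
             col_group[k + 1L] == col_group[j]) k <- k + 1L
      bid <- bid + 1L
      toks <- apply(aln[, j:k, drop = FALSE], 2L, function(col) col[!is.na(col)][1L])
      out <- rbind(out, data.frame(
        block_id = paste0("block", bid), group = col_group[j],
        start_col = j, end_col = k, length = k - j + 1L,
        tokens = paste(toks, collapse = ","), stringsAsFactors = FALSE))
      j <- k + 1L
    } else j <- j + 1L
  }
  out
}

#' SNP-bearing spacer variant groups
#'
#' Groups equal-length canonical spacers by single-linkage clustering at
#' Hamming distance at most `max_snps`; only groups with at least two
#' distinct variants are reported. For each variant the carrying strains and
#' locations are listed, with a flag for location-exclusive variants
#' (mirroring conserved spacers that differ only by location-specific
#' substitutions).
#'
#' @param catalog a `spacer_catalog`.
#' @param metadata strain metadata with `location`.
#' @param max_snps maximum pairwise Hamming distance for linkage.
#' @return list of variant groups, each with `length`, `n_variants`,
#'   `polymorphic_positions` (1-based), and `members` (data.frame `variant`,
#'   `n_strains`, `strains`, `locations`, `location_exclusive`).
#' @export
find_spacer_variants <- function(catalog, metadata, max_snps = 3L) {
  tab <- catalog$table
  groups_out <- list()
  for (len in sort(unique(tab$length))) {
    seqs <- sort(tab$canonical[tab$length == len])
    n <- length(seqs)
    if (n < 2L) next
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    rc <- revcomp(seqs)
    # strand-aware distance: canonical folding is lexicographic, so two
    # near-identical spacers can fold to opposite strands
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- min(hamming_dist(seqs[i], seqs[j]), hamming_dist(seqs[i], rc[j]))
        if (d <= max_snps) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    for (r in sort(unique(roots))) {
      members <- seqs[roots == r]
      if (length(members) < 2L) next
      # orient members against the first one before locating polymorphisms
      oriented <- vapply(members, function(v) {
        if (hamming_dist(members[1L], v) <= hamming_dist(members[1L], revcomp(v))) v
        else revcomp(v)
      }, "", USE.NAMES = FALSE)
      mat <- do.call(rbind, strsplit(oriented, "", fixed = TRUE))
      poly <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
      mem <- do.call(rbind, lapply(members, function(v) {
        strains <- strsplit(tab$strains[tab$canonical == v], ",", fixed = TRUE)[[1L]]
        locs <- sort(unique(metadata$location[match(strains, metadata$strain_id)]))
        data.frame(variant = v, n_strains = length(strains),
                   strains = paste(strains, collapse = ","),
                   locations = paste(locs, collapse = ","),
                   location_exclusive = length(locs) == 1L,
                   stringsAsFactors = FALSE)
      }))
      groups_out[[length(groups_out) + 1L]] <- list(
        length = len, n_variants = length(members),
        polymorphic_positions = poly, members = mem)
    }
  }
  groups_out
}

#' Strain groups from a phylogeny
#'
#' Either the tips under a named internal node (that clade vs the rest), or
#' the groups obtained by cutting the tree at a given depth from the root
#' (connected components of the remaining subtrees).
#'
#' @param tree an `ape::phylo` tree with strain ids as tip labels.
#' @param node name of an internal node (uses `tree$node.label`).
#' @param depth cut depth from the root (edge-length units).
#' @return named list of character vectors of strain ids.
#' @export
clade_groups <- function(tree, node = NULL, depth = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(node)) {
    stopifnot(!is.null(tree$node.label))
    idx <- which(tree$node.label == node)
    if (length(idx) == 0L) stop("no internal node named ", node)
    clade <- ape::extract.clade(tree, ape::Ntip(tree) + idx)$tip.label
    return(list(clade = sort(clade), rest = sort(setdiff(tree$tip.label, clade))))
  }
  stopifnot(!is.null(depth))
  depths <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  # deepest edge crossing the cut defines each tip's group root
  root_of <- function(tip) {
    path <- tip
    cur <- tip
    repeat {
      parent <- tree$edge[tree$edge[, 2L] == cur, 1L]
      if (length(parent) == 0L) break
      path <- c(path, parent)
      cur <- parent
    }
    anc <- rev(path)  # root ... tip
    below <- anc[depths[anc] >= depth]
    if (length(below) == 0L) tip else below[1L]
  }
  roots <- vapply(seq_len(ntip), root_of, 0L)
  groups <- split(tree$tip.label, roots)
  names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, sort)
}
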