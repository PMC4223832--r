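#' Simulation parameters for synthetic multi-strain genome sets
#'
#' Defaults emulate the study conditions of a Salinispora-style survey:
#' GC-rich (70%) genomes, an average of 4.4 CRISPR arrays per strain, 60%
#' of arrays cas-associated, subtype-specific repeat lengths of 29 nt
#' (I-E, I-B) and 37 nt (I-C and the I-U designations), most I-E arrays
#' paired around internal cas genes, 68% of distinct spacers observed once,
#' 11% of distinct spacers with a perfect prophage protospacer, 1.1% with a
#' known-MGE protospacer, 40% of shared spacers restricted to one location
#' or biome, a four-strain clade carrying one homologous locus with three
#' subclade-specific spacer blocks, and a conserved 41-nt spacer with
#' location-specific SNP variants (3 + 1 + 1 across three sites). Genome
#' length and strain count are desk-scale (10 strains of 1 Mb).
#'
#' @param seed mandatory RNG seed.
#' @param n_strains number of strains.
#' @param genome_length genome length per strain (bp).
#' @param gc background GC fraction.
#' @param arrays_per_strain_mean Poisson mean of arrays per strain (min 1;
#'   clade strains get at least 2 so the clade locus never displaces all
#'   generic arrays).
#' @param spacers_per_array inclusive range of spacers per generic array.
#' @param spacer_len_range inclusive spacer length range (nt).
#' @param repeat_mutation_rate per-base mutation rate applied independently
#'   to every planted repeat occurrence.
#' @param cas_assoc_prob probability that an array has an adjacent cas
#'   cluster.
#' @param paired_prob_ie probability that a cas-associated I-E array is
#'   planted as a paired locus (second array with inverted repeats).
#' @param prophages_per_strain_mean Poisson mean of prophages per strain.
#' @param prophage_length prophage region length (bp).
#' @param n_mge,mge_length known-MGE database size and record length.
#' @param protospacer_rate fraction of distinct spacers given a perfect
#'   protospacer inside a prophage (deterministic rounding).
#' @param mge_match_rate fraction of distinct spacers given a perfect
#'   protospacer inside a known-MGE record.
#' @param partial_rate fraction of distinct spacers whose central
#'   `partial_len` nt are copied into a known-MGE record (partial hits).
#' @param partial_len planted partial span (>= 18 nt).
#' @param self_target_rate fraction of distinct spacers copied into a
#'   housekeeping gene of a carrying strain (self-targeting).
#' @param unique_fraction target fraction of distinct spacers observed in
#'   one strain only.
#' @param location_restricted_rate target fraction of shared spacers
#'   restricted to one location/biome (deterministic planting).
#' @param ic_gc GC fraction used for I-C cas clusters (lower than the
#'   genomic background, as for horizontally acquired arrays).
#' @param clade plant the four-strain clade locus with three
#'   subclade-specific blocks (auto-disabled when fewer than four strains of
#'   the first species exist).
#' @param clade_backbone,clade_block_lens backbone length and the three
#'   block lengths of the clade locus.
#' @param variants plant the SNP spacer-variant group (auto-disabled when
#'   the location plan cannot host it).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_strains = 10L,
                              genome_length = 1e6,
                              gc = 0.70,
                              arrays_per_strain_mean = 4.4,
                              spacers_per_array = c(8L, 25L),
                              spacer_len_range = c(35L, 44L),
                              repeat_mutation_rate = 0,
                              cas_assoc_prob = 0.6,
                              paired_prob_ie = 0.6,
                              prophages_per_strain_mean = 1.5,
                              prophage_length = 10000L,
                              n_mge = 20L, mge_length = 5000L,
                              protospacer_rate = 0.11,
                              mge_match_rate = 0.011,
                              partial_rate = 0.05,
                              partial_len = 24L,
                              self_target_rate = 0.02,
                              unique_fraction = 0.68,
                              location_restricted_rate = 0.40,
                              ic_gc = 0.642,
                              clade = TRUE,
                              clade_backbone = 10L,
                              clade_block_lens = c(4L, 3L, 3L),
                              variants = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(repeat_mutation_rate, cas_assoc_prob, paired_prob_ie,
             protospacer_rate, mge_match_rate, partial_rate, self_target_rate,
             unique_fraction, location_restricted_rate)
  stopifnot(all(rates >= 0 & rates <= 1), partial_len >= 18L)
  structure(cfg, class = "simulation_config")
}

repeat_len_for_subtype <- function(subtype) {
  if (subtype %in% c("I-E", "I-B")) 29L else 37L
}

subtype_gene_order <- function(subtype) {
  switch(subtype,
    "I-E" = c("cas3", "cse1", "cse2", "cas7", "cas5", "cas6", "cas1", "cas2"),
    "I-C" = c("cas3", "cas8c", "cas7", "cas5", "cas4", "cas1", "cas2"),
    "I-B" = c("cas3", "cst1-like", "cas7", "cas5", "cas6", "cas4", "cas1", "cas2"),
    "I-U_csb3" = c("cas3", "csb3", "csb1", "csb2", "cas1", "cas2"),
    "I-U_csx17" = c("cas3", "csx17", "csb2"),
    "I-U_Sa" = c("cas3", "csb1", "csb2"),
    stop("unknown subtype ", subtype))
}

sim_locations <- function() {
  data.frame(
    location = c("Fiji", "Hawaii", "Palau", "Sea of Cortez", "Bahamas",
                 "Palmyra", "Madeira"),
    biome = c("Tropical Pacific", "Tropical Pacific", "Tropical Pacific",
              "Coastal", "Tropical Atlantic", "Tropical Pacific",
              "Temperate Atlantic"),
    latitude = c(-17.7, 21.3, 7.3, 27.0, 24.7, 5.9, 32.7),
    longitude = c(178.0, -157.9, 134.5, -111.0, -76.8, -162.1, -16.9),
    stringsAsFactors = FALSE
  )
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Rearrange a strain's generic arrays so that no array has unanimous spacer
# first or last characters: such a column is indistinguishable from a
# conserved repeat column, which would make the planted array boundary
# ambiguous. Spacers are swapped between the strain's generic arrays (the
# clade locus is fixed across strains and left untouched).
fix_unanimous_edges <- function(arr_tokens, plan) {
  generic <- which(vapply(plan, function(a) a$kind != "clade", TRUE))
  slots <- list()  # (array index, field) pairs holding swappable vectors
  for (i in generic) {
    slots[[length(slots) + 1L]] <- list(i = i, f = "main")
    if (!is.null(arr_tokens[[i]]$second)) {
      slots[[length(slots) + 1L]] <- list(i = i, f = "second")
    }
  }
  edge <- function(v, side) {
    if (side == "first") substr(v, 1L, 1L) else substr(v, nchar(v), nchar(v))
  }
  for (side in c("first", "last")) {
    for (si in seq_along(slots)) {
      s <- slots[[si]]
      v <- arr_tokens[[s$i]][[s$f]]
      if (length(v) < 2L) next
      if (length(unique(edge(v, side))) > 1L) next
      for (sj in seq_along(slots)) {
        if (sj == si) next
        d <- slots[[sj]]
        w <- arr_tokens[[d$i]][[d$f]]
        cand <- which(edge(w, side) != edge(v[1L], side))
        if (length(cand) > 0L) {
          tmp <- v[1L]
          v[1L] <- w[cand[1L]]
          w[cand[1L]] <- tmp
          arr_tokens[[s$i]][[s$f]] <- v
          arr_tokens[[d$i]][[d$f]] <- w
          break
        }
      }
    }
  }
  arr_tokens
}

# draw a pool of mutually distinct random spacers
draw_distinct_spacers <- function(n, len_range, gc, taken = character(0)) {
  out <- character(0)
  seen <- c(taken, canonical_spacer(taken))
  while (length(out) < n) {
    s <- random_dna(sample(len_range[1L]:len_range[2L], 1L), gc)
    cs <- canonical_spacer(s)
    if (!(cs %in% seen)) {
      out <- c(out, s)
      seen <- c(seen, cs)
    }
  }
  out
}

#' Simulate a multi-strain genome set with planted CRISPR-Cas features
#'
#' Generates genomes, gene annotations, strain metadata, prophage regions, a
#' known-MGE database, and a complete ground-truth manifest sufficient to
#' score every pipeline stage. Background sequence is i.i.d. at the
#' configured GC; repeats and spacers are drawn at random once and fixed in
#' the manifest; all planted features are non-overlapping and separated by
#' background. Deterministic given the config seed; with `out_dir` set, the
#' emitted files are byte-identical across reruns.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional output directory (`genomes/`, `annotations/`,
#'   `metadata.tsv`, `prophages.bed`, `prophages.fasta`, `mge_db.fasta`,
#'   `truth.json`).
#' @return a `crispr_simulation` list: `config`, `genomes`, `metadata`,
#'   `annotations` (per strain, 0-based half-open), `prophages`, `mge_db`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_strains
  strain_ids <- sprintf("SYN-%03d", seq_len(n))

  ## --- species / phylotype / location plan -------------------------------
  n_aren <- max(1L, round(n * 37 / 75))
  n_trop <- if (n >= 8L) max(1L, round(n * 7 / 75)) else 0L
  n_pac <- n - n_aren - n_trop
  species <- c(rep("S. arenicola", n_aren), rep("S. pacifica", n_pac),
               rep("S. tropica", n_trop))
  do_clade <- isTRUE(cfg$clade) && n_aren >= 4L
  phylotype <- character(n)
  phylotype[species == "S. arenicola"] <- rep(c("A", "ST"), length.out = n_aren)
  phylotype[species == "S. pacifica"] <- rep(c("A", "C", "F"), length.out = n_pac)
  phylotype[species == "S. tropica"] <- "ST1"
  clade_strains <- character(0)
  subclade1 <- subclade2 <- character(0)
  if (do_clade) {
    clade_strains <- strain_ids[1:4]
    subclade1 <- clade_strains[1:2]
    subclade2 <- clade_strains[3:4]
    phylotype[1:4] <- "B"
  }

  loc_tab <- sim_locations()
  location <- character(n)
  i <- 1L
  if (do_clade) { location[1:4] <- "Fiji"; i <- 5L }
  n_hw <- min(3L, n - i + 1L)
  if (n_hw > 0L) { location[i:(i + n_hw - 1L)] <- "Hawaii"; i <- i + n_hw }
  if (i <= n) { location[i] <- "Palau"; i <- i + 1L }
  if (i <= n) {
    location[i:n] <- rep(c("Sea of Cortez", "Bahamas", "Palmyra"),
                         length.out = n - i + 1L)
  }
  biome <- loc_tab$biome[match(location, loc_tab$location)]
  do_variants <- isTRUE(cfg$variants) && do_clade &&
    sum(location == "Hawaii") >= 3L && sum(location == "Palau") >= 1L

  metadata <- data.frame(
    strain_id = strain_ids, species = species, phylotype = phylotype,
    location = location, biome = biome,
    latitude = loc_tab$latitude[match(location, loc_tab$location)],
    longitude = loc_tab$longitude[match(location, loc_tab$location)],
    depth = 5 + 3 * seq_len(n),
    date = sprintf("2003-%02d-15", 1L + (seq_len(n) - 1L) %% 12L),
    gene_count = NA_integer_,
    stringsAsFactors = FALSE
  )

  ## --- subtype repeats ----------------------------------------------------
  subtypes <- c("I-E", "I-C", "I-B", "I-U_csb3", "I-U_csx17", "I-U_Sa")
  sub_repeat <- vapply(subtypes, function(s) random_dna(repeat_len_for_subtype(s), cfg$gc), "")
  clade_repeat <- random_dna(33L, cfg$gc)

  ## --- per-strain array plan ---------------------------------------------
  sub_prob <- c("I-E" = 0.34, "I-C" = 0.18, "I-B" = 0.14,
                "I-U_csb3" = 0.12, "I-U_csx17" = 0.10, "I-U_Sa" = 0.12)
  plans <- list()
  for (si in seq_len(n)) {
    sid <- strain_ids[si]
    k <- max(1L, stats::rpois(1L, cfg$arrays_per_strain_mean))
    is_clade <- sid %in% clade_strains
    if (is_clade) k <- max(2L, k)
    arrays <- list()
    n_generic <- k - as.integer(is_clade)
    for (ai in seq_len(n_generic)) {
      pr <- sub_prob
      if (species[si] != "S. arenicola") pr["I-U_Sa"] <- 0
      st <- sample(names(pr), 1L, prob = pr / sum(pr))
      cas <- stats::runif(1L) < cfg$cas_assoc_prob
      paired <- st == "I-E" && cas && stats::runif(1L) < cfg$paired_prob_ie
      size <- sample(cfg$spacers_per_array[1L]:cfg$spacers_per_array[2L], 1L)
      size2 <- if (paired) sample(cfg$spacers_per_array[1L]:cfg$spacers_per_array[2L], 1L) else 0L
      arrays[[length(arrays) + 1L]] <- list(kind = "generic", subtype = st,
                                            cas = cas, paired = paired,
                                            size = size, size2 = size2)
    }
    if (is_clade) {
      arrays[[length(arrays) + 1L]] <- list(kind = "clade", subtype = "I-E",
                                            cas = TRUE, paired = FALSE,
                                            size = NA_integer_, size2 = 0L)
    }
    plans[[sid]] <- arrays
  }

  ## --- clade locus tokens -------------------------------------------------
  clade_tokens <- list()
  clade_truth_blocks <- list()
  if (do_clade) {
    bl <- cfg$clade_block_lens
    backbone <- draw_distinct_spacers(cfg$clade_backbone, cfg$spacer_len_range, cfg$gc)
    blocks <- lapply(bl, function(L) draw_distinct_spacers(L, cfg$spacer_len_range, cfg$gc,
                                                           taken = backbone))
    # layout trailer->leader: B0 blk1 B1 blk2 B2 blk3 B3 (blocks 1,3 in
    # subclade 1; block 2 in subclade 2)
    seg <- split(backbone, rep(1:4, length.out = cfg$clade_backbone))
    mk <- function(with1, with2, with3) {
      c(seg[[1L]], if (with1) blocks[[1L]], seg[[2L]], if (with2) blocks[[2L]],
        seg[[3L]], if (with3) blocks[[3L]], seg[[4L]])
    }
    for (s in subclade1) clade_tokens[[s]] <- mk(TRUE, FALSE, TRUE)
    for (s in subclade2) clade_tokens[[s]] <- mk(FALSE, TRUE, FALSE)
    clade_truth_blocks <- list(
      list(group = "subclade1", tokens = canonical_spacer(blocks[[1L]])),
      list(group = "subclade2", tokens = canonical_spacer(blocks[[2L]])),
      list(group = "subclade1", tokens = canonical_spacer(blocks[[3L]]))
    )
  }

  ## --- variant group ------------------------------------------------------
  variant_truth <- NULL
  variant_by_strain <- list()
  if (do_variants) {
    core <- random_dna(41L, cfg$gc)
    poly <- sort(sample(seq_len(41L), 3L))
    mut_at <- function(seq, pos_set) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      for (p in pos_set) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      paste(chars, collapse = "")
    }
    hw <- strain_ids[location == "Hawaii"][1:3]
    pa <- strain_ids[location == "Palau"][1L]
    v_hw <- c(mut_at(core, poly[1L]), mut_at(core, poly[2L]), mut_at(core, poly[3L]))
    v_fj <- core
    v_pa <- mut_at(core, poly[1:2])
    stopifnot(length(unique(canonical_spacer(c(v_hw, v_fj, v_pa)))) == 5L)
    for (k in 1:3) variant_by_strain[[hw[k]]] <- c(variant_by_strain[[hw[k]]], v_hw[k])
    for (s in clade_strains) variant_by_strain[[s]] <- c(variant_by_strain[[s]], v_fj)
    variant_by_strain[[pa]] <- c(variant_by_strain[[pa]], v_pa)
    variant_truth <- list(length = 41L,
                          variants = canonical_spacer(c(v_hw, v_fj, v_pa)),
                          locations = c("Hawaii", "Hawaii", "Hawaii", "Fiji", "Palau"),
                          n_variants = 5L)
  }

  ## --- shared/unique pool bookkeeping ------------------------------------
  slot_count <- vapply(strain_ids, function(sid) {
    s <- sum(vapply(plans[[sid]], function(a) {
      if (a$kind == "clade") 0L else a$size + a$size2
    }, 0L))
    s - length(variant_by_strain[[sid]] %||% character(0))
  }, 0L)
  T_slots <- sum(slot_count)
  # extras already planted: clade tokens (each shared within the clade,
  # Fiji-restricted) and the variant spacers
  extra_shared_restricted <- if (do_clade) cfg$clade_backbone + sum(cfg$clade_block_lens) else 0L
  extra_shared <- extra_shared_restricted + as.integer(do_variants)  # Fiji variant shared
  extra_unique <- if (do_variants) 4L else 0L
  u0 <- cfg$unique_fraction
  Y <- max(0L, round((T_slots * (1 - u0) - (extra_shared + extra_unique) * u0 +
                        extra_unique) / (2 - u0)))
  Y <- min(Y, T_slots %/% 2L)
  X <- T_slots - 2L * Y

  taken <- c(unlist(clade_tokens), unlist(variant_by_strain))

  # capacity-aware assignment of shared spacers to strain pairs: restricted
  # pairs share one location, unrestricted pairs span two biomes (falling
  # back to two locations, then any two strains, when the plan lacks them)
  n_shared_target <- Y + extra_shared
  target_restricted <- round(cfg$location_restricted_rate * n_shared_target)
  need_restricted <- max(0L, min(Y, target_restricted - extra_shared_restricted -
                                   as.integer(do_variants)))
  cap <- slot_count
  pick2 <- function(idx) {
    ord <- idx[order(-cap[idx], idx)]
    ord[1:2]
  }
  shared_assign <- list()
  for (k in seq_len(Y)) {
    avail <- which(cap >= 1L)
    if (length(avail) < 2L) break
    pair <- NULL
    if (k <= need_restricted) {
      locs <- table(location[avail])
      locs <- names(locs)[locs >= 2L]
      if (length(locs) > 0L) {
        loc <- locs[1L + (k - 1L) %% length(locs)]
        pair <- pick2(avail[location[avail] == loc])
      }
    }
    if (is.null(pair)) {
      a <- avail[order(-cap[avail], avail)][1L]
      others <- setdiff(avail, a)
      b_cand <- others[biome[others] != biome[a]]
      if (length(b_cand) == 0L) b_cand <- others[location[others] != location[a]]
      if (length(b_cand) == 0L) b_cand <- others
      b <- b_cand[order(-cap[b_cand], b_cand)][1L]
      pair <- c(a, b)
    }
    cap[pair] <- cap[pair] - 1L
    shared_assign[[k]] <- strain_ids[pair]
  }
  Y <- length(shared_assign)
  X <- T_slots - 2L * Y
  shared_pool <- draw_distinct_spacers(Y, cfg$spacer_len_range, cfg$gc, taken = taken)
  unique_pool <- draw_distinct_spacers(X, cfg$spacer_len_range, cfg$gc,
                                       taken = c(taken, shared_pool))
  n_shared_total <- Y + extra_shared

  # distribute spacers to strain queues
  queue <- stats::setNames(vector("list", n), strain_ids)
  for (k in seq_len(Y)) {
    for (s in shared_assign[[k]]) queue[[s]] <- c(queue[[s]], shared_pool[k])
  }
  ui <- 0L
  for (sid in strain_ids) {
    need <- slot_count[[sid]] - length(queue[[sid]])
    if (need < 0L) stop("internal: strain ", sid, " oversubscribed with shared spacers")
    if (need > 0L) {
      queue[[sid]] <- c(queue[[sid]], unique_pool[(ui + 1L):(ui + need)])
      ui <- ui + need
    }
    queue[[sid]] <- sample(queue[[sid]])
  }

  ## --- per-array token lists ---------------------------------------------
  tokens_by_array <- list()  # [[sid]][[ai]] = list(main=chr, second=chr or NULL)
  for (sid in strain_ids) {
    q <- queue[[sid]]
    vq <- variant_by_strain[[sid]] %||% character(0)
    arr_tokens <- list()
    for (ai in seq_along(plans[[sid]])) {
      a <- plans[[sid]][[ai]]
      if (a$kind == "clade") {
        arr_tokens[[ai]] <- list(main = clade_tokens[[sid]], second = NULL)
        next
      }
      nv <- if (ai == 1L) length(vq) else 0L
      take <- a$size - nv
      main <- q[seq_len(take)]; q <- q[-seq_len(take)]
      if (nv > 0L) {
        at <- max(1L, a$size %/% 2L)
        main <- append(main, vq, after = min(at, length(main)))
      }
      second <- NULL
      if (a$paired) {
        second <- q[seq_len(a$size2)]; q <- q[-seq_len(a$size2)]
      }
      arr_tokens[[ai]] <- list(main = main, second = second)
    }
    stopifnot(length(q) == 0L)
    tokens_by_array[[sid]] <- fix_unanimous_edges(arr_tokens, plans[[sid]])
  }

  ## --- planting selections ------------------------------------------------
  all_distinct <- unique(canonical_spacer(c(shared_pool, unique_pool, taken)))
  D_total <- length(all_distinct)
  carrier <- stats::setNames(vector("list", length(all_distinct)), all_distinct)
  for (sid in strain_ids) {
    for (at in tokens_by_array[[sid]]) {
      for (tok in canonical_spacer(c(at$main, at$second))) {
        carrier[[tok]] <- unique(c(carrier[[tok]], sid))
      }
    }
  }
  shuffled <- sample(all_distinct)
  n_pro <- round(cfg$protospacer_rate * D_total)
  n_mge_hit <- round(cfg$mge_match_rate * D_total)
  n_part <- round(cfg$partial_rate * D_total)
  n_self <- round(cfg$self_target_rate * D_total)
  pro_sp <- shuffled[seq_len(n_pro)]
  mge_sp <- shuffled[n_pro + seq_len(n_mge_hit)]
  part_sp <- shuffled[n_pro + n_mge_hit + seq_len(n_part)]
  self_sp <- shuffled[n_pro + n_mge_hit + n_part + seq_len(n_self)]

  ## --- prophage plan ------------------------------------------------------
  pro_counts <- vapply(seq_len(n), function(i) stats::rpois(1L, cfg$prophages_per_strain_mean), 0L)
  if (sum(pro_counts) == 0L) pro_counts[1L] <- 1L
  pro_plan <- list()
  for (si in seq_len(n)) {
    for (k in seq_len(pro_counts[si])) {
      pro_plan[[length(pro_plan) + 1L]] <- list(
        id = sprintf("PRO_%s_%d", strain_ids[si], k),
        strain = strain_ids[si],
        family = if ((length(pro_plan) %% 3L) == 0L) "SV1" else "unclassified",
        plant = character(0))
    }
  }
  # assign protospacers to prophages, preferring a prophage of a strain that
  # does not carry the spacer
  pi_rr <- 0L
  pro_strains <- vapply(pro_plan, function(p) p$strain, "")
  for (sp in pro_sp) {
    pref <- which(!(pro_strains %in% carrier[[sp]]))
    pool <- if (length(pref)) pref else seq_along(pro_plan)
    pi_rr <- pi_rr + 1L
    tgt <- pool[1L + (pi_rr - 1L) %% length(pool)]
    pro_plan[[tgt]]$plant <- c(pro_plan[[tgt]]$plant, sp)
  }

  ## --- MGE database -------------------------------------------------------
  mge_ids <- sprintf("MGE_%03d", seq_len(cfg$n_mge))
  mge_family <- rep(c("plasmid", "phage"), length.out = cfg$n_mge)
  mge_seq <- vapply(seq_len(cfg$n_mge), function(i) random_dna(cfg$mge_length, 0.55), "")
  truth_hits <- list()
  plant_into <- function(seqs, idx, insert, offset) {
    substr(seqs[idx], offset + 1L, offset + nchar(insert)) <- insert
    seqs
  }
  off_rr <- stats::setNames(rep(400L, cfg$n_mge), mge_ids)
  mi <- 0L
  for (sp in mge_sp) {
    mi <- mi + 1L
    idx <- 1L + (mi - 1L) %% cfg$n_mge
    ins <- if (mi %% 2L == 0L) revcomp(sp) else sp
    off <- off_rr[[mge_ids[idx]]]
    mge_seq <- plant_into(mge_seq, idx, ins, off)
    off_rr[[mge_ids[idx]]] <- off + nchar(ins) + 120L
    truth_hits[[length(truth_hits) + 1L]] <- list(
      canonical = sp, target_id = mge_ids[idx], target_class = "known_MGE",
      category = "perfect", offset = off, length = nchar(sp))
  }
  for (sp in part_sp) {
    mi <- mi + 1L
    idx <- 1L + (mi - 1L) %% cfg$n_mge
    st <- (nchar(sp) - cfg$partial_len) %/% 2L
    frag <- substr(sp, st + 1L, st + cfg$partial_len)
    off <- off_rr[[mge_ids[idx]]]
    mge_seq <- plant_into(mge_seq, idx, frag, off)
    off_rr[[mge_ids[idx]]] <- off + nchar(frag) + 120L
    truth_hits[[length(truth_hits) + 1L]] <- list(
      canonical = sp, target_id = mge_ids[idx], target_class = "known_MGE",
      category = "partial", offset = off, length = cfg$partial_len)
  }
  mge_db <- data.frame(region_id = mge_ids, strain_id = NA_character_,
                       contig_id = NA_character_, start = NA_integer_,
                       end = NA_integer_, sequence = mge_seq,
                       class = "known_MGE", family = mge_family,
                       intact = TRUE, stringsAsFactors = FALSE)

  ## --- self-target plan ---------------------------------------------------
  self_plan <- list()
  host_genes <- c("purB" = "adenylosuccinate lyase",
                  "rlmB" = "23S rRNA methyltransferase",
                  "cyp450" = "cytochrome P450")
  for (k in seq_along(self_sp)) {
    sp <- self_sp[k]
    sid <- carrier[[sp]][1L]
    gene <- names(host_genes)[1L + (k - 1L) %% length(host_genes)]
    self_plan[[length(self_plan) + 1L]] <- list(
      strain = sid, canonical = sp, gene = gene, product = unname(host_genes[gene]))
  }

  ## --- assemble genomes ---------------------------------------------------
  genomes <- list()
  annotations <- list()
  truth_loci <- list()
  truth_clusters <- list()
  truth_prophages <- list()
  prophages_rows <- list()

  # pick the genomic spacer string for a token in a strain (the planted
  # instance equals the drawn string; paired second arrays plant revcomps)
  for (si in seq_len(n)) {
    sid <- strain_ids[si]
    contig <- paste0(sid, "_chr")
    parts <- character(0)
    pos <- 0L
    ann <- list()
    add <- function(s) { parts[length(parts) + 1L] <<- s; pos <<- pos + nchar(s) }
    bg <- function(len) add(random_dna(len, cfg$gc))

    strain_pros <- Filter(function(p) p$strain == sid, pro_plan)
    arr_list <- plans[[sid]]
    tok_list <- tokens_by_array[[sid]]
    cl_i <- 0L

    for (ai in seq_along(arr_list)) {
      a <- arr_list[[ai]]
      bg(1500L + sample(0:2500, 1L))
      rep_seq <- if (a$kind == "clade") clade_repeat else sub_repeat[[a$subtype]]
      toks <- tok_list[[ai]]$main

      # the single background bases flanking the array are chosen to break
      # any chance unanimity of the spacer-edge columns, so planted array
      # boundaries are identifiable by column conservation
      build_array <- function(repseq, spacers) {
        flank_base <- function(chars) {
          cnt <- table(factor(chars, levels = c("A", "C", "G", "T")))
          names(cnt)[which.min(cnt)]
        }
        if (length(spacers) > 0L) {
          add(flank_base(substr(spacers, nchar(spacers), nchar(spacers))))
        }
        segs <- character(0)
        occs <- integer(0)
        p0 <- pos
        for (j in seq_len(length(spacers) + 1L)) {
          occ <- mutate_seq(repseq, cfg$repeat_mutation_rate)
          occs <- c(occs, p0 + sum(nchar(segs)))
          segs <- c(segs, occ)
          if (j <= length(spacers)) segs <- c(segs, spacers[j])
        }
        add(paste(segs, collapse = ""))
        res <- list(start = p0, end = pos, occ_starts = occs, rep_len = nchar(repseq))
        if (length(spacers) > 0L) {
          add(flank_base(substr(spacers, 1L, 1L)))
        }
        res
      }

      if (a$cas) {
        # [array, leader at right][gap][cas cluster]([gap][inverted array])
        arr <- build_array(rep_seq, toks)
        truth_loci[[length(truth_loci) + 1L]] <- list(
          strain_id = sid, contig_id = contig, start = arr$start, end = arr$end,
          repeat_seq = rep_seq, spacers = toks,
          tokens = canonical_spacer(toks), orientation = "leader_right",
          subtype = a$subtype, cas = TRUE, kind = a$kind)
        bg(200L)
        cl_start <- pos
        cl_i <- cl_i + 1L
        genes <- subtype_gene_order(a$subtype)
        gene_gc <- if (a$subtype == "I-C") cfg$ic_gc else cfg$gc
        for (gi in seq_along(genes)) {
          glen <- 900L + sample(0:600, 1L)
          gstart <- pos
          add(random_dna(glen, gene_gc))
          ann[[length(ann) + 1L]] <- data.frame(
            contig_id = contig, start = gstart, end = pos,
            strand = "+", name = genes[gi], product = paste("CRISPR-associated protein", genes[gi]),
            stringsAsFactors = FALSE)
          if (gi < length(genes)) bg(100L + sample(0:50, 1L))
        }
        truth_clusters[[length(truth_clusters) + 1L]] <- list(
          strain_id = sid, contig_id = contig, start = cl_start, end = pos,
          subtype = a$subtype, genes = genes)
        if (a$paired) {
          bg(200L)
          toks2 <- tok_list[[ai]]$second
          # leader at left (adjacent to cas): genomic order leader->trailer,
          # inverted repeats
          arr2 <- build_array(revcomp(rep_seq), revcomp(rev(toks2)))
          truth_loci[[length(truth_loci) + 1L]] <- list(
            strain_id = sid, contig_id = contig, start = arr2$start, end = arr2$end,
            repeat_seq = revcomp(rep_seq), spacers = toks2,
            tokens = canonical_spacer(toks2), orientation = "leader_left",
            subtype = a$subtype, cas = TRUE, kind = "paired_partner")
        }
      } else {
        arr <- build_array(rep_seq, toks)
        truth_loci[[length(truth_loci) + 1L]] <- list(
          strain_id = sid, contig_id = contig, start = arr$start, end = arr$end,
          repeat_seq = rep_seq, spacers = toks,
          tokens = canonical_spacer(toks), orientation = "unknown",
          subtype = a$subtype, cas = FALSE, kind = a$kind)
      }
    }

    ## prophages
    for (p in strain_pros) {
      bg(1500L + sample(0:2500, 1L))
      pseq <- random_dna(cfg$prophage_length, 0.62)
      off <- 500L
      for (sp in p$plant) {
        ins <- sp
        substr(pseq, off + 1L, off + nchar(ins)) <- ins
        truth_hits[[length(truth_hits) + 1L]] <- list(
          canonical = sp, target_id = p$id, target_class = "prophage",
          category = "perfect", offset = off, length = nchar(sp))
        off <- off + nchar(ins) + 150L
      }
      pstart <- pos
      add(pseq)
      prophages_rows[[length(prophages_rows) + 1L]] <- data.frame(
        region_id = p$id, strain_id = sid, contig_id = contig,
        start = pstart, end = pos, sequence = pseq, class = "prophage",
        family = p$family, intact = TRUE, stringsAsFactors = FALSE)
      truth_prophages[[length(truth_prophages) + 1L]] <- list(
        region_id = p$id, strain_id = sid, contig_id = contig,
        start = pstart, end = pos, family = p$family)
    }

    ## self-target genes
    for (stp in Filter(function(x) x$strain == sid, self_plan)) {
      bg(1500L + sample(0:1000, 1L))
      gstart <- pos
      add(random_dna(400L, cfg$gc))
      t_off <- pos
      add(stp$canonical)
      add(random_dna(400L, cfg$gc))
      ann[[length(ann) + 1L]] <- data.frame(
        contig_id = contig, start = gstart, end = pos, strand = "+",
        name = stp$gene, product = stp$product, stringsAsFactors = FALSE)
      truth_hits[[length(truth_hits) + 1L]] <- list(
        canonical = stp$canonical, target_id = contig, target_class = "self",
        category = "perfect", offset = t_off, length = nchar(stp$canonical),
        strain_id = sid, overlaps_prophage = FALSE)
    }

    if (pos > cfg$genome_length) {
      stop("genome_length too small for the planted features (need ", pos, " bp)")
    }
    bg(cfg$genome_length - pos)
    seqs <- paste(parts, collapse = "")
    ann_df <- if (length(ann)) do.call(rbind, ann) else
      data.frame(contig_id = character(0), start = integer(0), end = integer(0),
                 strand = character(0), name = character(0), product = character(0),
                 stringsAsFactors = FALSE)
    metadata$gene_count[si] <- nrow(ann_df)
    genomes[[sid]] <- genome_record(sid, stats::setNames(seqs, contig),
                                    gene_count = nrow(ann_df))
    annotations[[sid]] <- ann_df
  }

  prophages <- if (length(prophages_rows)) do.call(rbind, prophages_rows) else
    data.frame(region_id = character(0), strain_id = character(0),
               contig_id = character(0), start = integer(0), end = integer(0),
               sequence = character(0), class = character(0), family = character(0),
               intact = logical(0), stringsAsFactors = FALSE)

  ## restricted fraction from the actual strain assignments (authoritative
  ## even when the location plan cannot host unrestricted pairs)
  shared_sets <- lapply(seq_len(Y), function(k) shared_assign[[k]])
  if (do_clade) {
    shared_sets <- c(shared_sets,
                     rep(list(clade_strains), cfg$clade_backbone),
                     rep(list(subclade1), cfg$clade_block_lens[1L]),
                     rep(list(subclade2), cfg$clade_block_lens[2L]),
                     rep(list(subclade1), cfg$clade_block_lens[3L]))
  }
  if (do_variants) shared_sets <- c(shared_sets, list(clade_strains))
  n_shared_restricted <- sum(vapply(shared_sets, function(ss) {
    idx <- match(ss, strain_ids)
    length(unique(location[idx])) == 1L || length(unique(biome[idx])) == 1L
  }, TRUE))
  truth <- list(
    seed = cfg$seed,
    n_strains = n,
    loci = truth_loci,
    cas_clusters = truth_clusters,
    prophages = truth_prophages,
    hits = truth_hits,
    clade = if (do_clade) list(strains = clade_strains,
                               subclade1 = subclade1, subclade2 = subclade2,
                               repeat_seq = clade_repeat,
                               blocks = clade_truth_blocks) else NULL,
    variants = variant_truth,
    sharing = list(
      n_distinct = D_total,
      n_shared = n_shared_total,
      n_unique = D_total - n_shared_total,
      unique_fraction = round((D_total - n_shared_total) / D_total, 4),
      n_shared_restricted = n_shared_restricted,
      restricted_fraction = round(100 * n_shared_restricted / max(1L, n_shared_total), 1)
    ),
    planted_rates = list(
      prophage_match = list(n = n_pro, spacers = pro_sp),
      mge_match = list(n = n_mge_hit, spacers = mge_sp),
      partial_match = list(n = n_part, spacers = part_sp),
      self_target = list(n = n_self, spacers = self_sp)
    )
  )

  sim <- structure(list(config = cfg, genomes = genomes, metadata = metadata,
                        annotations = annotations, prophages = prophages,
                        mge_db = mge_db, truth = truth),
                   class = "crispr_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' @rdname simulate_dataset
#' @param sim a `crispr_simulation`.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  for (sid in names(sim$genomes)) {
    g <- sim$genomes[[sid]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$contigs),
                                file.path(out_dir, "genomes", paste0(sid, ".fasta")))
    ann <- sim$annotations[[sid]]
    gff_path <- file.path(out_dir, "annotations", paste0(sid, ".gff3"))
    if (nrow(ann) > 0L) {
      lines <- sprintf("%s\tspacerscape_sim\tgene\t%d\t%d\t.\t%s\t.\tID=gene%d;Name=%s;product=%s",
                       ann$contig_id, ann$start + 1L, ann$end, ann$strand,
                       seq_len(nrow(ann)), ann$name, gsub(" ", "%20", ann$product))
      writeLines(c("##gff-version 3", lines), gff_path)
    } else {
      writeLines("##gff-version 3", gff_path)
    }
  }
  utils::write.table(sim$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- sim$prophages
  if (nrow(pp) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", pp$contig_id, pp$start, pp$end, pp$region_id),
               file.path(out_dir, "prophages.bed"))
    hdr <- sprintf("%s class=prophage family=%s strain=%s intact=yes",
                   pp$region_id, pp$family, pp$strain_id)
    ss <- Biostrings::DNAStringSet(stats::setNames(pp$sequence, hdr))
    Biostrings::writeXStringSet(ss, file.path(out_dir, "prophages.fasta"))
  } else {
    writeLines(character(0), file.path(out_dir, "prophages.bed"))
    writeLines(character(0), file.path(out_dir, "prophages.fasta"))
  }
  hdr <- sprintf("%s class=known_MGE family=%s", sim$mge_db$region_id, sim$mge_db$family)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(stats::setNames(sim$mge_db$sequence, hdr)),
                              file.path(out_dir, "mge_db.fasta"))
  writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  ov >= 0.5 * (e1 - s1) && ov >= 0.5 * (e2 - s2)
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Score pipeline outputs against the simulation truth
#'
#' Per feature class: precision, recall and F1. Loci match their planted
#' counterpart by at least 50% reciprocal overlap on the same contig;
#' spacers by (strain, canonical sequence); subtype labels by the matched
#' cas-associated locus; hits by (canonical, target, class, category);
#' blocks by their exact token run; variants by group membership.
#'
#' @param results output of [run_pipeline()].
#' @param truth the `truth` component of a `crispr_simulation`.
#' @return data.frame with columns `class`, `n_truth`, `n_detected`,
#'   `precision`, `recall`, `f1`.
#' @export
score_against_truth <- function(results, truth) {
  out <- list()
  add <- function(class, n_truth, n_detected, scores) {
    out[[length(out) + 1L]] <<- data.frame(
      class = class, n_truth = n_truth, n_detected = n_detected,
      precision = round(unname(scores["precision"]), 4),
      recall = round(unname(scores["recall"]), 4),
      f1 = round(unname(scores["f1"]), 4), stringsAsFactors = FALSE)
  }

  # loci (confirmed only)
  det <- Filter(function(l) l$confidence == "confirmed", results$loci)
  matched_truth <- logical(length(truth$loci))
  matched_det <- logical(length(det))
  for (ti in seq_along(truth$loci)) {
    tl <- truth$loci[[ti]]
    for (di in seq_along(det)) {
      dl <- det[[di]]
      if (matched_det[di]) next
      if (dl$strain_id == tl$strain_id && dl$contig_id == tl$contig_id &&
          reciprocal_overlap(dl$start, dl$end, tl$start, tl$end)) {
        matched_truth[ti] <- TRUE
        matched_det[di] <- TRUE
        break
      }
    }
  }
  add("loci", length(truth$loci), length(det),
      prf(sum(matched_truth), sum(!matched_det), sum(!matched_truth)))

  # spacers by (strain, canonical)
  truth_sp <- unique(unlist(lapply(truth$loci, function(l) {
    paste(l$strain_id, l$tokens, sep = "::")
  })))
  det_sp <- unique(paste(results$records$strain_id, results$records$canonical, sep = "::"))
  add("spacers", length(truth_sp), length(det_sp),
      prf(length(intersect(truth_sp, det_sp)),
          length(setdiff(det_sp, truth_sp)),
          length(setdiff(truth_sp, det_sp))))

  # subtype labels on cas clusters (interval overlap on same contig)
  ct <- results$clusters_table
  tp <- fp <- fn <- 0L
  for (tc in truth$cas_clusters) {
    hit <- which(ct$strain_id == tc$strain_id & ct$contig_id == tc$contig_id &
                   ct$start < tc$end & tc$start < ct$end)
    if (length(hit) == 0L) { fn <- fn + 1L; next }
    if (any(ct$subtype[hit] == tc$subtype)) tp <- tp + 1L else fp <- fp + 1L
  }
  extra <- nrow(ct) - (tp + fp)
  add("subtypes", length(truth$cas_clusters), nrow(ct), prf(tp, fp + max(0L, extra), fn))

  # planted hits
  canon_of <- stats::setNames(results$records$canonical, results$records$spacer_id)
  det_hits <- rbind(results$hits,
                    results$self_hits[, names(empty_hits()), drop = FALSE])
  det_keys <- unique(paste(canon_of[det_hits$spacer_id], det_hits$target_id,
                           det_hits$target_class, det_hits$category, sep = "::"))
  truth_keys <- unique(vapply(truth$hits, function(h) {
    paste(h$canonical, h$target_id, h$target_class, h$category, sep = "::")
  }, ""))
  add("hits", length(truth_keys), length(det_keys),
      prf(length(intersect(truth_keys, det_keys)),
          length(setdiff(det_keys, truth_keys)),
          length(setdiff(truth_keys, det_keys))))

  # clade blocks
  if (!is.null(truth$clade) && !is.null(results$blocks)) {
    truth_blocks <- vapply(truth$clade$blocks, function(b) paste(b$tokens, collapse = ","), "")
    det_blocks <- results$blocks$tokens
    add("blocks", length(truth_blocks), length(det_blocks),
        prf(length(intersect(truth_blocks, det_blocks)),
            length(setdiff(det_blocks, truth_blocks)),
            length(setdiff(truth_blocks, det_blocks))))
  }

  # variant group recovery
  if (!is.null(truth$variants) && !is.null(results$variants)) {
    want <- sort(truth$variants$variants)
    found <- any(vapply(results$variants, function(g) {
      all(want %in% g$members$variant)
    }, TRUE))
    add("variants", 1L, length(results$variants),
        c(precision = NA_real_, recall = as.numeric(found), f1 = NA_real_))
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
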