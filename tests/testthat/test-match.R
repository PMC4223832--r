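test_that("published self-targeting spacers match their chromosomal regions as reported", {
  ex <- self_targeting_examples()

  # adenylosuccinate lyase: one perfect full-coverage hit at 0-based offset 7
  h1 <- perfect_match(c(sp = ex$spacer[1]), c(t = ex$region[1]))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$strand, "+")
  expect_equal(h1$target_offset, 7)
  expect_equal(h1$match_length, nchar(ex$spacer[1]))

  # 23S rRNA methyltransferase: same structure
  h2 <- perfect_match(c(sp = ex$spacer[2]), c(t = ex$region[2]))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$target_offset, 7)
  expect_equal(h2$match_length, nchar(ex$spacer[2]))

  # cytochrome P450 (CNX-481): no perfect hit, one partial hit of 32 nt
  h3p <- perfect_match(c(sp = ex$spacer[3]), c(t = ex$region[3]))
  expect_equal(nrow(h3p), 0)
  h3 <- partial_match(c(sp = ex$spacer[3]), c(t = ex$region[3]))
  best <- h3[which.max(h3$match_length), ]
  expect_equal(best$match_length, 32)
  expect_gte(best$match_length, 18)
})

test_that("matching is strand-symmetric and silent on unrelated sequence", {
  set.seed(4401)
  sp <- random_dna(40, 0.5)
  target <- paste0(random_dna(200, 0.5), sp, random_dna(200, 0.5))
  fwd <- perfect_match(c(q = sp), c(t = target))
  rev <- perfect_match(c(q = sp), c(t = revcomp(target)))
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  # mirrored offset: start on revcomp target = len - end
  expect_equal(rev$target_offset, nchar(target) - (fwd$target_offset + 40))

  expect_equal(nrow(perfect_match(c(q = sp), c(t = random_dna(2000, 0.5)))), 0)
})

test_that("partial matching honours the length floor and the perfect-hit exclusion", {
  set.seed(4402)
  sp <- random_dna(40, 0.5)
  # spacer equal to target: perfect, never partial
  expect_equal(nrow(partial_match(c(q = sp), c(t = sp))), 0)
  expect_equal(nrow(perfect_match(c(q = sp), c(t = sp))), 1)

  # a 10-nt shared run is below the floor
  t10 <- paste0(random_dna(100, 0.5), substr(sp, 10, 19), random_dna(100, 0.5))
  h <- partial_match(c(q = sp), c(t = t10))
  expect_true(all(h$match_length >= 18))

  # a planted central 24-mer with mismatching flank bases yields exactly 24
  frag <- substr(sp, 9, 32)
  flank_l <- setdiff(c("A", "C", "G", "T"), substr(sp, 8, 8))[1]
  flank_r <- setdiff(c("A", "C", "G", "T"), substr(sp, 33, 33))[1]
  tgt <- paste0(random_dna(50, 0.5), flank_l, frag, flank_r, random_dna(50, 0.5))
  h24 <- partial_match(c(q = sp), c(t = tgt))
  expect_true(any(h24$match_length == 24 & h24$strand == "+"))
})

test_that("perfect and partial matching agree with the sliding-window oracle", {
  set.seed(4403)
  for (i in 1:40) {
    sp <- random_dna(sample(20:45, 1), 0.5)
    tlen <- sample(300:1500, 1)
    target <- random_dna(tlen, 0.5)
    mode <- i %% 4
    if (mode == 1) {  # plant the spacer
      off <- sample(0:(tlen - nchar(sp)), 1)
      substr(target, off + 1, off + nchar(sp)) <- sp
    } else if (mode == 2) {  # plant its reverse complement
      off <- sample(0:(tlen - nchar(sp)), 1)
      substr(target, off + 1, off + nchar(sp)) <- revcomp(sp)
    } else if (mode == 3) {  # plant a central fragment
      k <- sample(18:(nchar(sp) - 2), 1)
      st <- (nchar(sp) - k) %/% 2
      substr(target, 101, 100 + k) <- substr(sp, st + 1, st + k)
    }
    got_p <- perfect_match(c(q = sp), c(t = target))
    exp_p <- oracle_perfect(sp, target)
    expect_equal(nrow(got_p), nrow(exp_p))
    if (nrow(exp_p)) {
      expect_equal(got_p$target_offset, sort(exp_p$offset0))
    }
    got_f <- partial_match(c(q = sp), c(t = target))
    exp_f <- oracle_partial(sp, target)
    expect_equal(
      sort(paste(got_f$strand, got_f$target_offset, got_f$match_length)),
      sort(paste(exp_f$strand, exp_f$offset0, exp_f$len)))
  }
})

test_that("self-targeting scan excludes the locus and flags prophage overlaps", {
  fx <- fixture_planted_sequence(bg = 600, seed = 4404)
  sp1 <- fx$spacers[1]
  sp2 <- fx$spacers[2]
  set.seed(4405)
  gene <- paste0(random_dna(300, 0.5), sp1, random_dna(300, 0.5))
  prophage <- paste0(random_dna(400, 0.5), sp2, random_dna(400, 0.5))
  genome_seq <- paste0(fx$seq, gene, random_dna(500, 0.5), prophage,
                       random_dna(500, 0.5))
  g <- genome_record("S", c(c1 = genome_seq))
  loci <- find_candidate_arrays(g)
  expect_length(loci, 1)
  rec <- extract_spacers(loci)
  pro_start <- nchar(fx$seq) + nchar(gene) + 500
  pro <- data.frame(region_id = "P1", strain_id = "S", contig_id = "c1",
                    start = pro_start, end = pro_start + nchar(prophage),
                    sequence = prophage, class = "prophage", family = "SV1",
                    intact = TRUE, stringsAsFactors = FALSE)

  hits <- self_targeting_scan(g, loci, rec, prophages = pro)
  expect_equal(nrow(hits), 2)
  by_sp <- hits[order(hits$target_offset), ]
  expect_false(by_sp$overlaps_prophage[1])  # the housekeeping-gene copy
  expect_true(by_sp$overlaps_prophage[2])   # the prophage-resident copy

  # spacers whose only occurrence is the locus itself yield nothing
  g0 <- genome_record("S", c(c1 = fx$seq))
  l0 <- find_candidate_arrays(g0)
  expect_equal(nrow(self_targeting_scan(g0, l0, extract_spacers(l0))), 0)
})

test_that("match summaries compute per-group distinct-spacer fractions", {
  rec <- data.frame(
    spacer_id = paste0("s", 1:10), strain_id = "A", locus_id = "l1",
    sequence = vapply(1:10, function(i) paste0(strrep("AC", 9), c("GT", "TG", "GA", "AT", "CC", "GG", "TA", "AG", "CT", "TC")[i]), ""),
    length = 20L, index_from_trailer = 0:9, index_from_leader = NA_integer_,
    cas_associated = TRUE, subtype_context = "I-E", stringsAsFactors = FALSE)
  rec$canonical <- canonical_spacer(rec$sequence)
  hits <- data.frame(spacer_id = paste0("s", 1:4), target_id = "P1",
                     target_class = "prophage", strand = "+", target_offset = 0L,
                     match_length = 20L, category = "perfect",
                     stringsAsFactors = FALSE)
  md <- data.frame(strain_id = "A", species = "S. x", stringsAsFactors = FALSE)
  ms <- match_summary(rec, hits, md)
  strain_row <- ms[ms$grouping == "strain", ]
  expect_equal(strain_row$n_spacers, 10)
  expect_equal(strain_row$pct_prophage, 40.0)
  expect_equal(strain_row$pct_known_mge, 0.0)

  # zero hits give 0%
  ms0 <- match_summary(rec, hits[0, ], md)
  expect_equal(ms0$pct_prophage[ms0$grouping == "strain"], 0.0)
})

test_that("encounter history reports positions, span, and leader-only flags", {
  rec <- data.frame(
    spacer_id = paste0("s", 0:9), strain_id = "A", locus_id = "L",
    sequence = strrep("ACGT", 10), canonical = strrep("ACGT", 10),
    length = 40L, index_from_trailer = 0:9, index_from_leader = 9:0,
    cas_associated = TRUE, subtype_context = "I-E", stringsAsFactors = FALSE)
  hit <- function(ids) data.frame(spacer_id = ids,
                                  target_id = rep("P", length(ids)),
                                  target_class = rep("prophage", length(ids)),
                                  strand = rep("+", length(ids)),
                                  target_offset = rep(0L, length(ids)),
                                  match_length = rep(40L, length(ids)),
                                  category = rep("perfect", length(ids)),
                                  stringsAsFactors = FALSE)

  eh <- encounter_history(rec, hit(c("s1", "s4", "s8")))
  expect_equal(eh$positions$index_from_trailer, c(1, 4, 8))
  expect_equal(eh$summary$span, 7)
  expect_false(eh$summary$recent_only)

  eh2 <- encounter_history(rec, hit(c("s8", "s9")))
  expect_equal(eh2$summary$span, 1)
  expect_true(eh2$summary$recent_only)

  eh0 <- encounter_history(rec, hit(character(0)))
  expect_equal(nrow(eh0$positions), 0)
})
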