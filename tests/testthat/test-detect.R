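test_that("a planted array is recovered with exact coordinates and spacers", {
  fx <- fixture_planted_sequence()
  loci <- find_candidate_arrays(genome_record("S1", c(c1 = fx$seq)))
  expect_length(loci, 1)
  l <- loci[[1]]
  expect_equal(l$confidence, "confirmed")
  expect_length(l$repeat_starts, 4)
  expect_length(l$spacer_starts, 3)
  expect_equal(l$start, fx$start)
  expect_equal(l$end, fx$end)
  expect_equal(l$spacers, fx$spacers)
  expect_equal(l$consensus, fixture_repeat)
})

test_that("random sequence yields no confirmed loci and tandem repeats are rejected", {
  set.seed(4150)
  neg <- find_candidate_arrays(genome_record("N", c(c1 = random_dna(10000, 0.5))))
  expect_length(Filter(function(l) l$confidence == "confirmed", neg), 0)

  tandem <- paste0(random_dna(1000, 0.5), strrep(fixture_repeat, 4),
                   random_dna(1000, 0.5))
  expect_length(find_candidate_arrays(genome_record("T", c(c1 = tandem))), 0)
})

test_that("confidence classification follows the repeat-count and spacer rules", {
  fx <- fixture_planted_sequence()
  loci <- find_candidate_arrays(genome_record("S1", c(c1 = fx$seq)))
  expect_equal(classify_confidence(loci[[1]]), "confirmed")

  # two repeats, one spacer: below the minimum of three occurrences
  R <- fixture_repeat
  set.seed(4151)
  two <- paste0(R, random_dna(35, 0.5), R)
  seq2 <- paste0(random_dna(500, 0.5), two, random_dna(500, 0.5))
  l2 <- make_locus(seq2, c(501, 501 + 67), 32)
  expect_equal(classify_confidence(l2), "questionable")

  # five repeats with identical spacers: spacer self-identity 1 > 0.8
  sp <- random_dna(35, 0.5)
  arr <- paste0(R, sp, R, sp, R, sp, R, sp, R)
  seq5 <- paste0(random_dna(500, 0.5), arr, random_dna(500, 0.5))
  l5 <- make_locus(seq5, 501 + 67 * (0:4), 32)
  expect_length(l5$repeat_starts, 5)
  expect_equal(classify_confidence(l5), "questionable")
})

test_that("adjacent loci merge across N-runs only when consensus repeats agree", {
  cfg <- detection_config()
  fxa <- fixture_planted_sequence(bg = 600, seed = 4160)
  arr_a <- substr(fxa$seq, 601, fxa$end)  # planted array text
  set.seed(4161)
  S2 <- c(paste0("A", random_dna(33, 0.5), "C"), paste0("C", random_dna(33, 0.5), "G"),
          paste0("G", random_dna(33, 0.5), "A"))
  R <- fixture_repeat
  arr_b <- paste0(R, S2[1], R, S2[2], R, S2[3], R)
  gap_n <- strrep("N", 500)
  left <- paste0(random_dna(599, 0.5), "T")
  right <- paste0("T", random_dna(599, 0.5))

  with_gap <- paste0(left, arr_a, gap_n, arr_b, right)
  loci <- find_candidate_arrays(genome_record("S", c(c1 = with_gap)))
  expect_length(loci, 2)
  merged <- merge_adjacent_loci(loci, with_gap, cfg)
  expect_length(merged, 1)
  m <- merged[[1]]
  expect_length(m$merged_from, 2)
  # repeats and spacers still alternate: spacers = repeats - 1
  expect_equal(length(m$spacer_starts), length(m$repeat_starts) - 1)
  expect_equal(m$start, loci[[1]]$start)
  expect_equal(m$end, loci[[2]]$end)

  # a same-length random (non-N) gap must not merge
  gap_r <- random_dna(500, 0.5)
  no_n <- paste0(left, arr_a, gap_r, arr_b, right)
  loci2 <- find_candidate_arrays(genome_record("S", c(c1 = no_n)))
  expect_length(merge_adjacent_loci(loci2, no_n, cfg), 2)

  # different consensus (3 substitutions) across an N gap must not merge
  R2 <- paste0("GGG", substr(R, 4, 32))
  arr_c <- paste0(R2, S2[1], R2, S2[2], R2, S2[3], R2)
  diff_cons <- paste0(left, arr_a, gap_n, arr_c, right)
  loci3 <- find_candidate_arrays(genome_record("S", c(c1 = diff_cons)))
  expect_length(loci3, 2)
  expect_length(merge_adjacent_loci(loci3, diff_cons, cfg), 2)
})

test_that("orientation uses the cas side, then the degenerate terminal repeat", {
  fx <- fixture_planted_sequence()
  l <- find_candidate_arrays(genome_record("S1", c(c1 = fx$seq)))[[1]]
  expect_equal(orient_locus(l, cas_side = "left")$orientation, "leader_left")
  expect_equal(orient_locus(l, cas_side = "right")$orientation, "leader_right")

  # all terminal identities equal -> unknown
  expect_equal(orient_locus(l)$orientation, "unknown")

  # degenerate last repeat (low identity) marks the trailer there
  l2 <- l
  l2$occ_identity <- c(0.97, 1, 1, 0.75)
  expect_equal(orient_locus(l2)$orientation, "leader_left")
  l3 <- l
  l3$occ_identity <- c(0.75, 1, 1, 0.97)
  expect_equal(orient_locus(l3)$orientation, "leader_right")
})

test_that("paired loci require flanking inverted consensus repeats around one cluster", {
  fx <- fixture_planted_sequence(bg = 500, seed = 4170)
  la <- find_candidate_arrays(genome_record("S", c(c1 = fx$seq)))[[1]]
  # build an inverted copy downstream of a fake cas cluster interval
  lb <- la
  lb$locus_id <- "S|c1|2"
  lb$consensus <- revcomp(la$consensus)
  span <- la$end - la$start
  lb$start <- la$end + 3000; lb$end <- lb$start + span
  cl <- make_cluster("S|cas1", "S", "c1", la$end + 300, la$end + 2700)
  pairs <- detect_paired_loci(list(la, lb), list(cl))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$left_locus, la$locus_id)
  expect_equal(pairs$right_locus, lb$locus_id)

  # same-orientation consensus on both sides: no pair
  lc <- lb; lc$consensus <- la$consensus
  expect_equal(nrow(detect_paired_loci(list(la, lc), list(cl))), 0)
  # single locus beside the cluster: no pair
  expect_equal(nrow(detect_paired_loci(list(la), list(cl))), 0)
})

test_that("repeat consensus is a majority vote with fixed tie order", {
  expect_equal(repeat_consensus(rep("ACGT", 3))$consensus, "ACGT")
  # one position split 2A/1G
  expect_equal(repeat_consensus(c("AAAA", "AAAA", "AGAA"))$consensus, "AAAA")
  # 2A/2G tie resolves to A (A < C < G < T)
  cons <- repeat_consensus(c("AAAA", "AAAA", "AGAA", "AGAA"))
  expect_equal(cons$consensus, "AAAA")
  expect_true(all(rowSums(cons$freq) == 4))
})

test_that("seeded detector equals the exhaustive scanner on short sequences", {
  for (seed in c(11, 23, 35, 47, 59)) {
    set.seed(seed)
    R <- random_dna(30, 0.5)
    k <- sample(3:5, 1)
    sp <- replicate(k, random_dna(sample(30:45, 1), 0.5))
    arr <- paste0(R, paste0(sp, R, collapse = ""))
    seqn <- paste0(random_dna(1500, 0.5), arr, random_dna(1500, 0.5))
    det <- find_candidate_arrays(genome_record("X", c(c1 = seqn)))
    bf <- brute_force_scan(seqn)
    expect_equal(length(det), length(bf))
    if (length(det) == 1 && length(bf) == 1) {
      expect_equal(det[[1]]$repeat_starts, bf[[1]]$repeat_starts)
      expect_equal(det[[1]]$repeat_ends, bf[[1]]$repeat_ends)
    }
    # negative control: both scanners stay silent on plain random sequence
    neg <- random_dna(4000, 0.6)
    expect_length(find_candidate_arrays(genome_record("N", c(c1 = neg))), 0)
    expect_length(brute_force_scan(neg), 0)
  }
})

test_that("detection is reverse-complement symmetric and spacer counts are consistent", {
  fx <- fixture_planted_sequence()
  fwd <- find_candidate_arrays(genome_record("S", c(c1 = fx$seq)))
  rev <- find_candidate_arrays(genome_record("S", c(c1 = revcomp(fx$seq))))
  expect_length(rev, 1)
  n <- nchar(fx$seq)
  expect_equal(rev[[1]]$start, n - fwd[[1]]$end)
  expect_equal(rev[[1]]$end, n - fwd[[1]]$start)
  expect_equal(rev[[1]]$consensus, revcomp(fwd[[1]]$consensus))
  expect_setequal(rev[[1]]$spacers, revcomp(fwd[[1]]$spacers))

  sim <- small_sim(4180)
  for (sid in names(sim$genomes)) {
    for (l in find_candidate_arrays(sim$genomes[[sid]])) {
      expect_equal(length(l$spacer_starts), length(l$repeat_starts) - 1)
    }
  }
})
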