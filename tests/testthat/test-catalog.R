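test_that("spacer indices follow the trailer/leader conventions", {
  fx <- fixture_planted_sequence()
  l <- find_candidate_arrays(genome_record("S1", c(c1 = fx$seq)))[[1]]

  l$orientation <- "leader_left"
  rec <- extract_spacers(list(l))
  # genomic left-to-right; leader at left means trailer indices count down
  expect_equal(rec$index_from_trailer, c(2, 1, 0))
  expect_equal(rec$index_from_leader, c(0, 1, 2))

  l$orientation <- "leader_right"
  rec <- extract_spacers(list(l))
  expect_equal(rec$index_from_trailer, c(0, 1, 2))
  expect_equal(rec$index_from_leader, c(2, 1, 0))

  l$orientation <- "unknown"
  rec <- extract_spacers(list(l))
  expect_true(all(is.na(rec$index_from_leader)))
  expect_equal(rec$index_from_trailer, c(0, 1, 2))
})

test_that("record counts are conserved across extraction", {
  sim <- small_sim(4301)
  loci <- list()
  for (sid in names(sim$genomes)) {
    loci <- c(loci, find_candidate_arrays(sim$genomes[[sid]]))
  }
  rec <- extract_spacers(loci)
  expect_equal(nrow(rec), sum(vapply(loci, function(l) length(l$spacer_starts), 0L)))
})

test_that("canonicalization is idempotent and strand-invariant", {
  set.seed(4302)
  for (i in 1:25) {
    s <- random_dna(sample(20:45, 1), runif(1, 0.3, 0.7))
    expect_equal(canonical_spacer(canonical_spacer(s)), canonical_spacer(s))
    expect_equal(canonical_spacer(revcomp(s)), canonical_spacer(s))
  }
})

test_that("sharing counts distinct strains, not copies", {
  base <- data.frame(
    spacer_id = paste0("r", 1:4),
    strain_id = c("A", "B", "C", "A"),
    locus_id = paste0("l", 1:4),
    sequence = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
                 "ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTG"),
    length = 21L, index_from_trailer = 0L, index_from_leader = NA_integer_,
    cas_associated = FALSE, subtype_context = NA_character_,
    stringsAsFactors = FALSE)
  base$canonical <- canonical_spacer(base$sequence)
  cat1 <- build_catalog(base)
  expect_equal(cat1$shared_count, 1)  # in A, B and C
  expect_equal(cat1$unique_count, 1)  # only in A

  # the same spacer twice in one strain is still unique
  dup <- base[c(1, 1), ]
  dup$spacer_id <- c("r1", "r1b"); dup$locus_id <- c("l1", "l1b")
  cat2 <- build_catalog(dup)
  expect_equal(cat2$shared_count, 0)
  expect_equal(cat2$unique_count, 1)

  # conservation: distinct canonicals = unique + shared
  expect_equal(nrow(cat1$table), cat1$unique_count + cat1$shared_count)
})

test_that("catalog unique/shared counts equal the generator manifest", {
  sim <- small_sim(4303)
  res <- suppressWarnings(run_pipeline(sim))
  expect_equal(res$catalog$unique_count + res$catalog$shared_count,
               sim$truth$sharing$n_distinct)
  expect_equal(res$catalog$shared_count, sim$truth$sharing$n_shared)
})

test_that("per-strain summaries normalize per Mb and are empty-safe", {
  g <- genome_record("S", c(c1 = strrep("ACGT", 1375000)))  # 5.5 Mb
  fx <- fixture_planted_sequence()
  l <- find_candidate_arrays(genome_record("S", c(c1 = fx$seq)))[[1]]
  loci <- lapply(1:9, function(i) { l$locus_id <- paste0("S|c1|", i); l })
  rec <- extract_spacers(loci)
  cat9 <- build_catalog(rec)
  tab <- per_strain_summary(cat9, loci, list(), list(S = g))
  expect_equal(tab$n_loci, 9)
  expect_equal(tab$loci_per_mb, 1.6)  # 9 / 5.5

  empty <- per_strain_summary(build_catalog(extract_spacers(list())),
                              list(), list(), list(S = g))
  expect_equal(empty$n_loci, 0)
  expect_equal(empty$loci_per_mb, 0)
  expect_equal(empty$pct_loci_cas, 0)
})
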