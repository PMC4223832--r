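test_that("simulation is deterministic given the seed", {
  s1 <- small_sim(4701)
  s2 <- small_sim(4701)
  expect_identical(lapply(s1$genomes, function(g) g$contigs),
                   lapply(s2$genomes, function(g) g$contigs))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$mge_db$sequence, s2$mge_db$sequence)

  s3 <- small_sim(4702)
  expect_false(identical(s1$genomes[[1]]$contigs, s3$genomes[[1]]$contigs))

  # files written from the same seed are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(small_sim(4703), d1)
  write_simulation(small_sim(4703), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 4)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("the manifest is consistent with the emitted sequences", {
  sim <- small_sim(4704)
  for (tl in sim$truth$loci) {
    contig <- sim$genomes[[tl$strain_id]]$contigs[[tl$contig_id]]
    slice <- substr(contig, tl$start + 1, tl$end)
    # truth spacers are recorded trailer-to-leader; a leader_left (inverted)
    # array runs leader-to-trailer on the forward strand
    genomic_spacers <- if (tl$orientation == "leader_left") {
      revcomp(rev(tl$spacers))
    } else tl$spacers
    expected <- paste0(tl$repeat_seq,
                       paste0(genomic_spacers, tl$repeat_seq, collapse = ""))
    expect_identical(slice, expected)
  }
  for (pp in seq_len(nrow(sim$prophages))) {
    row <- sim$prophages[pp, ]
    contig <- sim$genomes[[row$strain_id]]$contigs[[row$contig_id]]
    expect_identical(substr(contig, row$start + 1, row$end), row$sequence)
  }
})

test_that("protospacer planting counts follow deterministic rounding", {
  sim <- simulate_dataset(simulation_config(
    seed = 4705, n_strains = 4L, genome_length = 200000,
    arrays_per_strain_mean = 3, spacers_per_array = c(8L, 12L),
    protospacer_rate = 0.25, clade = FALSE, variants = FALSE))
  D <- sim$truth$sharing$n_distinct
  expect_equal(sim$truth$planted_rates$prophage_match$n, round(0.25 * D))
  planted <- Filter(function(h) h$target_class == "prophage", sim$truth$hits)
  expect_length(planted, round(0.25 * D))
})

test_that("a minimal one-strain simulation closes the loop with the detector", {
  sim <- simulate_dataset(simulation_config(
    seed = 4706, n_strains = 1L, genome_length = 30000,
    arrays_per_strain_mean = 1, spacers_per_array = c(3L, 3L),
    prophages_per_strain_mean = 0, protospacer_rate = 0, mge_match_rate = 0,
    partial_rate = 0, self_target_rate = 0, clade = FALSE, variants = FALSE))
  tl <- sim$truth$loci
  loci <- find_candidate_arrays(sim$genomes[[1]])
  expect_length(loci, length(tl))
  for (i in seq_along(tl)) {
    expect_equal(loci[[i]]$start, tl[[i]]$start)
    expect_equal(loci[[i]]$end, tl[[i]]$end)
    expect_equal(loci[[i]]$spacers, tl[[i]]$spacers)
  }
})

test_that("truth scoring computes precision and recall as expected", {
  sim <- small_sim(4707)
  res <- suppressWarnings(run_pipeline(sim))
  sc <- score_against_truth(res, sim$truth)
  expect_true(all(sc$recall[sc$class %in% c("loci", "spacers", "subtypes", "hits")] == 1))

  # disabling detection drives recall to zero
  res0 <- res
  res0$loci <- list()
  res0$records <- res$records[0, ]
  sc0 <- score_against_truth(res0, sim$truth)
  expect_equal(sc0$recall[sc0$class == "loci"], 0)

  # one spurious locus drops precision to n/(n+1)
  fake <- res$loci[[1]]
  fake$locus_id <- "FAKE"
  fake$strain_id <- names(sim$genomes)[1]
  fake$start <- 90000; fake$end <- 90400
  res1 <- res
  res1$loci <- c(res$loci, list(fake))
  sc1 <- score_against_truth(res1, sim$truth)
  n <- length(sim$truth$loci)
  expect_equal(sc1$precision[sc1$class == "loci"], round(n / (n + 1), 4))
})
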