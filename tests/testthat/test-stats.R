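test_that("location-restricted fraction handles the boundary cases", {
  mk_cat <- function(strain_sets) {
    seqs <- vapply(seq_along(strain_sets), function(i) {
      paste0(strrep("AC", 9), sprintf("%02d", i), collapse = "")
    }, "")
    seqs <- vapply(seq_along(strain_sets),
                   function(i) paste0(substr(strrep("ACGT", 6), 1, 18 + i), "A"), "")
    rows <- do.call(rbind, lapply(seq_along(strain_sets), function(i) {
      data.frame(spacer_id = paste0("s", i, "_", strain_sets[[i]]),
                 strain_id = strain_sets[[i]], locus_id = "l",
                 sequence = seqs[i], canonical = canonical_spacer(seqs[i]),
                 length = nchar(seqs[i]), index_from_trailer = 0L,
                 index_from_leader = NA_integer_, cas_associated = FALSE,
                 subtype_context = NA_character_, stringsAsFactors = FALSE)
    }))
    build_catalog(rows)
  }
  md <- data.frame(strain_id = c("A", "B", "C", "D"),
                   location = c("Fiji", "Fiji", "Hawaii", "Bahamas"),
                   biome = c("Pacific", "Pacific", "Pacific", "Atlantic"),
                   stringsAsFactors = FALSE)

  # all shared spacers span two locations and two biomes -> 0%
  all_wide <- mk_cat(list(c("A", "D"), c("C", "D")))
  expect_equal(location_restricted_fraction(all_wide, md)$fraction, 0)

  # all shared spacers confined to one location -> 100%
  all_tight <- mk_cat(list(c("A", "B"), c("A", "B")))
  expect_equal(location_restricted_fraction(all_tight, md)$fraction, 100)

  # same location always implies same biome here, so the OR keeps the
  # location-only spacer restricted; a two-location one-biome spacer is
  # restricted through its biome
  mixed <- mk_cat(list(c("A", "B"), c("A", "C"), c("A", "D")))
  got <- location_restricted_fraction(mixed, md)
  expect_equal(got$fraction, round(100 * 2 / 3, 1))

  # merging locations can only keep or grow the restricted set
  md2 <- md; md2$location[md2$location == "Hawaii"] <- "Fiji"
  expect_gte(location_restricted_fraction(mixed, md2)$fraction, got$fraction)
})

test_that("count normalization is elementwise and matches the scalar case", {
  expect_equal(normalize_counts(9, 5.5e6, "mb"), 9 / 5.5)
  expect_equal(normalize_counts(0, 5e6, "mb"), 0)
  expect_equal(normalize_counts(120, 4000, "gene"), 0.03)
  x <- c(3, 9, 0); s <- c(1e6, 5.5e6, 2e6)
  expect_equal(normalize_counts(x, s, "mb"),
               vapply(seq_along(x), function(i) normalize_counts(x[i], s[i], "mb"), 0))
})

test_that("rank tests are invariant to within-group permutations and consistent", {
  set.seed(4601)
  a <- rnorm(8); b <- rnorm(8) + 5
  h1 <- kruskal_wallis(list(a, b))
  h2 <- kruskal_wallis(list(sample(a), sample(b)))
  expect_equal(h1$statistic, h2$statistic)
  expect_equal(h1$p_value, h2$p_value)

  # well-separated groups: both tests significant; identical groups: neither
  w <- wilcoxon_ranksum(a, b)
  expect_lt(h1$p_value, 0.05)
  expect_lt(w$p_value, 0.05)
  h0 <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unname(h0$statistic), 0)
  w0 <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(w0$p_value, 0.05)

  # swapping the samples mirrors the rank sum and preserves p
  wa <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  wb <- wilcoxon_ranksum(c(3, 4), c(1, 2))
  expect_equal(wa$p_value, wb$p_value)
  expect_equal(unname(wa$statistic + wb$statistic), sum(1:4))
})

test_that("t statistic is scale-invariant and regression R2 matches correlation", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  t1 <- two_sample_t(a, b)
  t2 <- two_sample_t(3 * a, 3 * b)
  expect_equal(unname(t1$statistic), unname(t2$statistic))
  expect_equal(unname(two_sample_t(a, a + c(-1, 0, 1))$statistic), 0)

  set.seed(4602)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r <- least_squares_r2(x, y)
  expect_equal(r$r_squared, unname(cor(x, y)^2))
  expect_equal(least_squares_r2(x, 2 * x + 1)$r_squared, 1)
  expect_equal(least_squares_r2(x, rep(3, 30) + 0 * x)$r_squared, 0)
})

test_that("the battery gates pairwise tests on the omnibus result", {
  per_strain <- data.frame(
    strain_id = paste0("S", 1:8),
    genome_size = rep(1e6, 8),
    n_loci = c(1, 2, 1, 2, 9, 10, 9, 10),
    n_spacers = c(10, 20, 10, 20, 90, 100, 90, 100),
    stringsAsFactors = FALSE)
  md <- data.frame(strain_id = paste0("S", 1:8),
                   species = rep(c("low", "high"), each = 4),
                   location = rep("Fiji", 8), biome = rep("Pacific", 8),
                   stringsAsFactors = FALSE)
  tab <- suppressWarnings(run_stat_battery(per_strain, md))
  kw <- tab[tab$test == "kruskal_wallis" & tab$comparison == "loci_per_mb~species", ]
  expect_equal(nrow(kw), 1)
  expect_lt(kw$p_value, 0.05)
  # a significant omnibus triggers the pairwise rank-sum test
  expect_true(any(tab$test == "wilcoxon_ranksum" &
                    grepl("loci_per_mb~species", tab$comparison)))
  # single-level groupings (location, biome) are skipped
  expect_false(any(grepl("location", tab$comparison)))
})
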