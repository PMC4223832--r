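tok_array <- function(strain, locus, tokens) {
  list(strain_id = strain, locus_id = locus, tokens = tokens)
}

test_that("homologous loci require identical consensus plus a shared spacer", {
  fx <- fixture_planted_sequence()
  mk <- function(strain, consensus, spacers) {
    l <- find_candidate_arrays(genome_record(strain, c(c1 = fx$seq)))[[1]]
    l$strain_id <- strain
    l$locus_id <- paste0(strain, "|c1|1")
    l$consensus <- consensus
    rec <- extract_spacers(list(l))
    rec$canonical <- canonical_spacer(spacers)[seq_len(nrow(rec))]
    list(locus = l, rec = rec)
  }
  sp <- c("ACGTACGTACGTACGTACGTG", "TGCATGCATGCATGCATGCAA", "GGAAGGAAGGAAGGAAGGAAC")
  a <- mk("A", "AAACCCGGGTTTAAACCCGGG", sp)
  b <- mk("B", "AAACCCGGGTTTAAACCCGGG", sp)
  recs <- rbind(a$rec, b$rec)
  expect_length(find_homologous_loci(list(a$locus, b$locus), recs), 1)

  # zero shared spacers: separate singleton groups
  c2 <- mk("C", "AAACCCGGGTTTAAACCCGGG",
           c("TTTTTTTTTTGGGGGGGGGGA", "CCCCCCCCCCAAAAAAAAAAG", "GTGTGTGTGTGTGTGTGTGTC"))
  expect_length(find_homologous_loci(list(a$locus, c2$locus), rbind(a$rec, c2$rec)), 2)

  # consensus off by one nucleotide: separate groups even with shared spacers
  d <- mk("D", "TAACCCGGGTTTAAACCCGGG", sp)
  expect_length(find_homologous_loci(list(a$locus, d$locus), rbind(a$rec, d$rec)), 2)
})

test_that("token alignment places identical spacers in shared columns", {
  # identical arrays: all columns shared, no gaps
  al <- align_token_arrays(list(tok_array("A", "a", c("A", "B", "C")),
                                tok_array("B", "b", c("A", "B", "C"))))
  expect_equal(ncol(al$alignment), 3)
  expect_equal(al$shared_columns, 3)
  expect_false(anyNA(al$alignment))

  # hand-checked LCS: ABCDEF vs ABXYEF -> A B (C|-) (D|-) (-|X) (-|Y) E F
  al2 <- align_token_arrays(list(tok_array("g1", "l1", c("A", "B", "C", "D", "E", "F")),
                                 tok_array("g2", "l2", c("A", "B", "X", "Y", "E", "F"))))
  expect_equal(ncol(al2$alignment), 8)
  expect_equal(al2$shared_columns, 4)
  g1 <- al2$alignment["l1", ]
  g2 <- al2$alignment["l2", ]
  expect_equal(g1[!is.na(g1)], c("A", "B", "C", "D", "E", "F"), ignore_attr = TRUE)
  expect_equal(g2[!is.na(g2)], c("A", "B", "X", "Y", "E", "F"), ignore_attr = TRUE)

  # disjoint arrays share nothing
  al3 <- align_token_arrays(list(tok_array("A", "a", c("A", "B")),
                                 tok_array("B", "b", c("X", "Y"))))
  expect_equal(al3$shared_columns, 0)
})

test_that("group-specific blocks are maximal runs owned by exactly one group", {
  al <- align_token_arrays(list(tok_array("g1", "l1", c("A", "B", "C", "D", "E", "F")),
                                tok_array("g2", "l2", c("A", "B", "X", "Y", "E", "F"))))
  blocks <- group_specific_blocks(al, list(one = "g1", two = "g2"))
  expect_equal(nrow(blocks), 2)
  expect_setequal(blocks$tokens, c("C,D", "X,Y"))
  expect_setequal(blocks$group, c("one", "two"))

  # identical arrays produce no blocks
  al0 <- align_token_arrays(list(tok_array("g1", "l1", c("A", "B", "C")),
                                 tok_array("g2", "l2", c("A", "B", "C"))))
  expect_equal(nrow(group_specific_blocks(al0, list(one = "g1", two = "g2"))), 0)
})

test_that("token LCS equals the dynamic-programming oracle and is bounded", {
  set.seed(4501)
  alphabet <- paste0("t", 1:12)
  for (i in 1:30) {
    a <- sample(alphabet, sample(3:15, 1), replace = TRUE)
    b <- sample(alphabet, sample(3:15, 1), replace = TRUE)
    al <- align_token_arrays(list(tok_array("A", "a", a), tok_array("B", "b", b)))
    expect_equal(al$shared_columns, oracle_lcs_length(a, b))
    expect_lte(al$shared_columns, min(length(a), length(b)))
    # symmetry of the shared-column count
    al_swap <- align_token_arrays(list(tok_array("B", "b", b), tok_array("A", "a", a)))
    expect_equal(al_swap$shared_columns, al$shared_columns)
  }
})

test_that("SNP variant groups collect equal-length near-identical spacers", {
  md <- data.frame(strain_id = c("H1", "H2", "F1", "F2"),
                   location = c("Hawaii", "Hawaii", "Fiji", "Fiji"),
                   stringsAsFactors = FALSE)
  mk_cat <- function(seqs, strains) {
    rec <- data.frame(
      spacer_id = paste0("s", seq_along(seqs)), strain_id = strains,
      locus_id = paste0("l", seq_along(seqs)), sequence = seqs,
      canonical = canonical_spacer(seqs), length = nchar(seqs),
      index_from_trailer = 0L, index_from_leader = NA_integer_,
      cas_associated = FALSE, subtype_context = NA_character_,
      stringsAsFactors = FALSE)
    build_catalog(rec)
  }
  core <- "ACCTGACGGATTACCGGTTACCGATCCGGATTACCGGTACG"  # 41 nt
  var1 <- paste0("T", substr(core, 2, 41))            # 1 SNP
  g <- find_spacer_variants(mk_cat(c(core, var1), c("H1", "F1")), md)
  expect_length(g, 1)
  expect_equal(g[[1]]$n_variants, 2)
  expect_true(all(g[[1]]$members$location_exclusive))
  expect_equal(g[[1]]$length, 41)

  # identical spacers only: no group (needs >= 2 distinct variants)
  expect_length(find_spacer_variants(mk_cat(c(core, core), c("H1", "F1")), md), 0)

  # grouping is invariant to input order
  g_rev <- find_spacer_variants(mk_cat(c(var1, core), c("F1", "H1")), md)
  expect_equal(sort(g_rev[[1]]$members$variant), sort(g[[1]]$members$variant))
})

test_that("clade groups come from named nodes or depth cuts of a newick tree", {
  tree <- ape::read.tree(text = "((A:1,B:1)cladeAB:2,(C:1,D:1)cladeCD:2)root;")
  gr <- clade_groups(tree, node = "cladeAB")
  expect_equal(gr$clade, c("A", "B"))
  expect_equal(gr$rest, c("C", "D"))

  gr2 <- clade_groups(tree, depth = 1.5)
  expect_length(gr2, 2)
  expect_setequal(unlist(gr2), c("A", "B", "C", "D"))
})
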