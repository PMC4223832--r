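mk_genes <- function(names, contig = "c1", start = 1000, gap = 100, len = 900) {
  starts <- start + (seq_along(names) - 1) * (len + gap)
  data.frame(contig_id = contig, start = starts, end = starts + len,
             strand = "+", name = names, product = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("cas clusters are maximal runs split by gaps and intervening genes", {
  g <- mk_genes(c("cas3", "cse1", "cse2", "cas7", "cas5", "cas1", "cas2"))
  cl <- find_cas_clusters(g, "S")
  expect_length(cl, 1)
  expect_length(cl[[1]]$gene_names, 7)

  # a 5 kb gap after cse2 splits the run in two
  g2 <- g
  g2$start[4:7] <- g2$start[4:7] + 5000
  g2$end[4:7] <- g2$end[4:7] + 5000
  expect_length(find_cas_clusters(g2, "S"), 2)

  # a non-cas gene inside the run splits it even without a large gap
  g3 <- rbind(g[1:3, ], mk_genes("transposase", start = g$end[3] + 10)[1, ],
              g[4:7, ])
  g3$start[5:8] <- g3$end[4] + 10 + (0:3) * 1000
  g3$end[5:8] <- g3$start[5:8] + 900
  expect_length(find_cas_clusters(g3, "S"), 2)

  expect_length(find_cas_clusters(mk_genes(c("recA", "gyrB")), "S"), 0)
})

test_that("subtype classification matches signatures and never labels cas3-less clusters", {
  classify <- function(genes) {
    cl <- find_cas_clusters(mk_genes(genes), "S")[[1]]
    classify_subtype(cl)
  }
  expect_equal(classify(c("cas3", "cse1", "cse2", "cas7", "cas5", "cas1", "cas2"))$subtype, "I-E")
  expect_equal(classify(c("cas3", "csx17", "csb2"))$subtype, "I-U_csx17")
  expect_equal(classify(c("cas3", "csb3", "csb1", "csb2", "cas1", "cas2"))$subtype, "I-U_csb3")
  expect_equal(classify(c("cas3", "csb1", "csb2"))$subtype, "I-U_Sa")
  expect_equal(classify(c("cas3", "cas8c", "cas7", "cas5", "cas1", "cas2"))$subtype, "I-C")
  expect_equal(classify(c("cas3", "cst1-like", "cas7", "cas1", "cas2"))$subtype, "I-B")

  # no cas3 -> unclassified, whatever else is present
  expect_equal(classify(c("cse1", "cse2", "cas7", "cas1", "cas2"))$subtype, "unclassified")

  # empty cluster list for no genes; cluster with unknown-only genes never forms
  empty <- structure(list(cluster_id = "x", gene_names = character(0),
                          has_cas1 = FALSE, has_cas3 = FALSE),
                     class = "cas_cluster")
  expect_equal(classify_subtype(empty)$subtype, "unclassified")

  # cas1 forbids the cas1-less I-U designations
  with_cas1 <- classify(c("cas3", "csx17", "csb2", "cas1"))
  expect_false(with_cas1$subtype %in% c("I-U_csx17", "I-U_Sa"))
})

test_that("classification is invariant to gene order and tracks completeness", {
  genes <- c("cas3", "cas8c", "cas7", "cas5", "cas1", "cas2")
  set.seed(42)
  for (i in 1:5) {
    cl <- find_cas_clusters(mk_genes(sample(genes)), "S")[[1]]
    expect_equal(classify_subtype(cl)$subtype, "I-C")
  }
  # removing cas1/cas2 keeps the I-C label but flags the cluster incomplete
  cl <- classify_subtype(find_cas_clusters(mk_genes(c("cas3", "cas8c", "cas7", "cas5")), "S")[[1]])
  expect_equal(cl$subtype, "I-C")
  expect_false(cl$complete)
  # cas1-forbidding subtypes are complete without cas1/cas2
  cl2 <- classify_subtype(find_cas_clusters(mk_genes(c("cas3", "csx17", "csb2")), "S")[[1]])
  expect_true(cl2$complete)
})

test_that("gene-name normalization maps aliases case-insensitively", {
  expect_equal(normalize_gene_name(c("Cas8e", "CSD1", "cst1_like", "cas3")),
               c("cse1", "cas8c", "cst1-like", "cas3"))
})

test_that("loci associate with the nearest cluster within the distance cap", {
  fx <- fixture_planted_sequence(bg = 500, seed = 4201)
  l <- find_candidate_arrays(genome_record("S", c(c1 = fx$seq)))[[1]]
  near <- make_cluster("S|cas1", "S", "c1", l$end + 200, l$end + 2000)
  far <- make_cluster("S|cas2", "S", "c1", l$end + 5000, l$end + 7000)

  got <- associate_crispr_cas(list(l), list(near))
  expect_true(got$loci[[1]]$cas_associated)
  expect_equal(got$loci[[1]]$cluster_id, "S|cas1")

  got2 <- associate_crispr_cas(list(l), list(far))
  expect_false(got2$loci[[1]]$cas_associated)

  # paired loci flanking one cluster both associate with it
  l2 <- l
  l2$locus_id <- "S|c1|2"
  l2$start <- near$end + 300; l2$end <- l2$start + (l$end - l$start)
  got3 <- associate_crispr_cas(list(l, l2), list(near))
  expect_true(all(vapply(got3$loci, function(x) x$cas_associated, TRUE)))
})

test_that("gc_contrast computes region and genome GC to 0.1 percent", {
  g <- genome_record("S", c(c1 = "GGCCGATCAT"))
  expect_equal(gc_contrast(g, "c1", 0, 4)$region_gc, 100.0)  # GGCC
  expect_equal(gc_contrast(g, "c1", 4, 8)$region_gc, 50.0)   # GATC
  expect_error(gc_contrast(g, "c1", 4, 4), "empty")
})
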