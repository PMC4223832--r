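# Shared fixtures built in code.

# A clean planted array: fixed 32-nt repeat, three distinct 35-nt spacers
# whose first and last characters differ from each other, embedded in random
# background with single disambiguating flank bases, so the planted
# boundaries are exactly identifiable.
fixture_repeat <- "ATCGGCACGTTGACCTGATCGGATCAACGGTC"

fixture_spacers <- function() {
  set.seed(4101)
  c(paste0("A", random_dna(33, 0.5), "A"),
    paste0("C", random_dna(33, 0.5), "C"),
    paste0("G", random_dna(33, 0.5), "G"))
}

# returns list(seq, start, end, spacers) with 0-based half-open coordinates
fixture_planted_sequence <- function(bg = 2000, seed = 4102) {
  set.seed(seed)
  S <- fixture_spacers()
  R <- fixture_repeat
  arr <- paste0(R, S[1], R, S[2], R, S[3], R)
  left <- paste0(random_dna(bg - 1, 0.5), "T")
  right <- paste0("T", random_dna(bg - 1, 0.5))
  list(seq = paste0(left, arr, right),
       start = bg, end = bg + nchar(arr), spacers = S)
}

# a crispr_locus built directly from occurrence starts on a sequence
make_locus <- function(seq, starts1, rep_len, strain = "S", contig = "c") {
  l <- spacerscape:::build_locus(seq, starts1, rep_len, strain, contig)
  l$locus_id <- paste(strain, contig, "1", sep = "|")
  l
}

# minimal cas cluster stub for association/pairing tests
make_cluster <- function(id, strain, contig, start, end, genes = c("cas3", "cse1", "cse2")) {
  structure(list(cluster_id = id, strain_id = strain, contig_id = contig,
                 start = start, end = end,
                 genes = data.frame(), gene_names = genes,
                 subtype = NA_character_, complete = NA,
                 has_cas1 = "cas1" %in% genes, has_cas3 = "cas3" %in% genes),
            class = "cas_cluster")
}

# small fast simulation for unit tests
small_sim <- function(seed, ...) {
  simulate_dataset(simulation_config(
    seed = seed, n_strains = 3L, genome_length = 120000,
    arrays_per_strain_mean = 2, spacers_per_array = c(4L, 8L),
    prophages_per_strain_mean = 1, clade = FALSE, variants = FALSE, ...))
}
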