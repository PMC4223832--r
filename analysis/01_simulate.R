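#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-strain study.
#
# Ten 1-Mb genomes emulating a Salinispora-style survey: ~4.4 CRISPR arrays
# per strain with six cas subtypes, prophages, a known-MGE database, planted
# protospacers, a four-strain clade with subclade-specific spacer blocks,
# and location-structured spacer sharing. Bulky sequence data goes under
# scratch/ (not a deliverable); tables under results/.

suppressPackageStartupMessages(library(spacerscape))
dir.create("scratch/state", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 11)
sim <- simulate_dataset(cfg, out_dir = "scratch/sim")
saveRDS(sim, "scratch/state/sim.rds")

write.table(sim$metadata, "results/strains.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d strains (%s), %d planted loci, %d prophages, %d MGE records",
                length(sim$genomes),
                paste(table(sim$metadata$species), collapse = "/"),
                length(sim$truth$loci), nrow(sim$prophages), nrow(sim$mge_db)))
message(sprintf("planted sharing: %d distinct spacers, %.1f%% unique, %.1f%% of shared location/biome-restricted",
                sim$truth$sharing$n_distinct,
                100 * sim$truth$sharing$unique_fraction,
                sim$truth$sharing$restricted_fraction))
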