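#!/usr/bin/env Rscript
# Stage 8: species-level summary, recovery scoring against the generator
# manifest, and the consolidated report.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
loci <- readRDS("scratch/state/loci.rds")
clusters <- readRDS("scratch/state/clusters.rds")
st <- readRDS("scratch/state/catalog.rds")
mt <- readRDS("scratch/state/matching.rds")
cp <- readRDS("scratch/state/compare.rds")
bg <- readRDS("scratch/state/biogeo.rds")

sp_sum <- species_summary(st$per_strain, sim$metadata, mt$msum, sim$prophages)
write.table(sp_sum, "results/species_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

results <- list(
  genomes = sim$genomes, metadata = sim$metadata,
  loci = loci, loci_table = loci_table(loci),
  clusters = clusters, clusters_table = clusters_table(clusters),
  records = st$records, catalog = st$catalog,
  hits = mt$hits, self_hits = mt$self_hits, match_summary = mt$msum,
  per_strain = st$per_strain, species_summary = sp_sum,
  alignment = cp$alignment, blocks = cp$blocks, variants = cp$variants,
  sharing = bg$sharing, stats = bg$stats
)
write_report(results, "scratch/report")  # full report incl. per-spacer tables

recovery <- score_against_truth(results, sim$truth)
write.table(recovery, "results/recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("per-species summary:")
for (i in seq_len(nrow(sp_sum))) {
  message(sprintf("  %s: %d genomes, %d loci (%.1f/strain), %d spacers, %.1f%% matching prophages",
                  sp_sum$species[i], sp_sum$n_genomes[i], sp_sum$total_crisprs[i],
                  sp_sum$loci_per_strain[i], sp_sum$total_spacers[i],
                  sp_sum$pct_spacers_prophage[i]))
}
message("recovery vs generator manifest:")
for (i in seq_len(nrow(recovery))) {
  message(sprintf("  %-9s precision=%s recall=%s", recovery$class[i],
                  format(recovery$precision[i]), format(recovery$recall[i])))
}
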