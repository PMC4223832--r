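#!/usr/bin/env Rscript
# Stage 7: biogeographic sharing and the statistical battery.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
st <- readRDS("scratch/state/catalog.rds")
mt <- readRDS("scratch/state/matching.rds")

sharing <- location_restricted_fraction(st$catalog, sim$metadata)
stats_tab <- run_stat_battery(st$per_strain, sim$metadata, sim$prophages,
                              mt$msum[mt$msum$grouping == "strain", ])
saveRDS(list(sharing = sharing, stats = stats_tab), "scratch/state/biogeo.rds")

write.table(sharing$table, "results/sharing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(stats_tab, "results/stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%.1f%% of the %d shared spacers are restricted to one location and/or biome (location only: %.1f%%, biome only: %.1f%%)",
                sharing$fraction, sharing$n_shared,
                sharing$fraction_location, sharing$fraction_biome))
sig <- stats_tab[stats_tab$p_value < 0.05, ]
message(sprintf("statistical battery: %d tests, %d significant at 0.05 (no multiplicity correction)",
                nrow(stats_tab), nrow(sig)))
for (i in seq_len(min(5, nrow(sig)))) {
  message(sprintf("  %s [%s]: stat=%.3f p=%.3g", sig$test[i], sig$comparison[i],
                  sig$statistic[i], sig$p_value[i]))
}
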