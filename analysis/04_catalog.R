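#!/usr/bin/env Rscript
# Stage 4: spacer extraction, canonical deduplication, per-strain summary.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
loci <- readRDS("scratch/state/loci.rds")
clusters <- readRDS("scratch/state/clusters.rds")

confirmed <- Filter(function(l) l$confidence == "confirmed", loci)
records <- extract_spacers(confirmed)
catalog <- build_catalog(records)
per_strain <- per_strain_summary(catalog, confirmed, clusters, sim$genomes)
saveRDS(list(records = records, catalog = catalog, per_strain = per_strain),
        "scratch/state/catalog.rds")

write.table(catalog$table, "results/spacer_catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(per_strain, "results/per_strain.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_distinct <- catalog$unique_count + catalog$shared_count
message(sprintf("%d spacer records; %d distinct canonical spacers, %.0f%% observed in a single strain",
                nrow(records), n_distinct,
                100 * catalog$unique_count / n_distinct))
message(sprintf("strand-folded vs raw sharing: %d vs %d shared sequences",
                catalog$shared_count, catalog$raw_shared_count))
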