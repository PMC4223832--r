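#!/usr/bin/env Rscript
# Stage 2: de-novo repeat-spacer array detection with assembly-gap merging.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")

cfg <- detection_config()
loci <- list()
for (sid in names(sim$genomes)) {
  g <- sim$genomes[[sid]]
  found <- find_candidate_arrays(g, cfg)
  for (ctg in names(g$contigs)) {
    on_ctg <- Filter(function(l) l$contig_id == ctg, found)
    loci <- c(loci, merge_adjacent_loci(on_ctg, g$contigs[[ctg]], cfg))
  }
}
saveRDS(loci, "scratch/state/loci.rds")

tab <- loci_table(loci)
write.table(tab, "results/loci.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

conf <- tab[tab$confidence == "confirmed", ]
message(sprintf("detected %d loci (%d confirmed), %.1f per strain, mean locus size %.0f bp",
                nrow(tab), nrow(conf), nrow(conf) / length(sim$genomes),
                mean(conf$locus_size)))
message(sprintf("repeat lengths span %d-%d nt across subtype repeats",
                min(conf$repeat_len), max(conf$repeat_len)))
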