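#!/usr/bin/env Rscript
# Stage 5: spacer-protospacer matching (prophages, known MGEs, self) and
# the encounter history of the SV1-like prophage family.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
loci <- readRDS("scratch/state/loci.rds")
st <- readRDS("scratch/state/catalog.rds")

confirmed <- Filter(function(l) l$confidence == "confirmed", loci)
hits <- rbind(perfect_match(st$catalog$records, sim$prophages),
              perfect_match(st$catalog$records, sim$mge_db),
              partial_match(st$catalog$records, sim$mge_db))
self_hits <- do.call(rbind, lapply(names(sim$genomes), function(sid) {
  self_targeting_scan(sim$genomes[[sid]],
                      Filter(function(l) l$strain_id == sid, confirmed),
                      st$catalog$records, sim$prophages)
}))
msum <- match_summary(st$catalog$records, hits, sim$metadata)
history <- encounter_history(st$catalog$records, hits,
                             targets = sim$prophages, family = "SV1")
saveRDS(list(hits = hits, self_hits = self_hits, msum = msum,
             history = history), "scratch/state/matching.rds")

write.table(hits, "results/hits.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(self_hits, "results/self_hits.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(msum, "results/match_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(history$summary, "results/encounter_history.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sp_row <- msum[msum$grouping == "cas", ]
message(sprintf("%d perfect + %d partial hits; self-targeting hits: %d (%d inside prophages)",
                sum(hits$category == "perfect"), sum(hits$category == "partial"),
                nrow(self_hits), sum(self_hits$overlaps_prophage)))
for (i in seq_len(nrow(sp_row))) {
  message(sprintf("  %s spacers: %.1f%% match prophages, %.1f%% match known MGEs",
                  sp_row$group[i], sp_row$pct_prophage[i], sp_row$pct_known_mge[i]))
}
if (nrow(history$summary)) {
  message(sprintf("SV1-like encounter history: %d arrays with matches, max span %d positions",
                  nrow(history$summary), max(history$summary$span)))
}
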