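#!/usr/bin/env Rscript
# Stage 3: cas cluster detection, subtype classification, locus association,
# orientation, paired loci, and the I-C GC contrast.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
loci <- readRDS("scratch/state/loci.rds")

clusters <- list()
for (sid in names(sim$genomes)) {
  cls <- find_cas_clusters(sim$annotations[[sid]], sid)
  clusters <- c(clusters, lapply(cls, classify_subtype))
}
assoc <- associate_crispr_cas(loci, clusters)
loci <- assoc$loci
cl_by_id <- setNames(clusters, vapply(clusters, function(c) c$cluster_id, ""))
for (i in seq_along(loci)) {
  l <- loci[[i]]
  if (isTRUE(l$cas_associated)) {
    cl <- cl_by_id[[l$cluster_id]]
    loci[[i]] <- orient_locus(l, cas_side = if (cl$start >= l$end) "right" else "left")
  } else {
    loci[[i]] <- orient_locus(l)
  }
}
pairs <- detect_paired_loci(loci, clusters)
saveRDS(loci, "scratch/state/loci.rds")
saveRDS(clusters, "scratch/state/clusters.rds")

ct <- clusters_table(clusters)
write.table(ct, "results/cas_clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pairs, "results/paired_loci.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

# GC contrast of I-C clusters vs their genomes (horizontally acquired
# arrays sit below the genomic GC background)
gc_rows <- list()
for (cl in clusters) {
  if (is.na(cl$subtype) || cl$subtype != "I-C") next
  gc <- gc_contrast(sim$genomes[[cl$strain_id]], cl$contig_id, cl$start, cl$end)
  gc_rows[[length(gc_rows) + 1L]] <- data.frame(
    cluster_id = cl$cluster_id, region_gc = gc$region_gc,
    genome_gc = gc$genome_gc, difference = gc$difference)
}
if (length(gc_rows)) {
  gc_tab <- do.call(rbind, gc_rows)
  write.table(gc_tab, "results/gc_contrast_ic.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("I-C clusters: mean GC %.1f%% vs genome %.1f%% (difference %.1f points)",
                  mean(gc_tab$region_gc), mean(gc_tab$genome_gc),
                  mean(gc_tab$difference)))
}
message(sprintf("%d cas clusters across %d subtypes; %d/%d loci cas-associated; %d paired loci",
                nrow(ct), length(unique(ct$subtype)),
                sum(vapply(loci, function(l) isTRUE(l$cas_associated), TRUE)),
                length(loci), nrow(pairs)))
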