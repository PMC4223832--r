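#!/usr/bin/env Rscript
# Stage 6: homologous-locus alignment across the four-strain clade,
# subclade-specific spacer blocks, and SNP spacer variants.

suppressPackageStartupMessages(library(spacerscape))
sim <- readRDS("scratch/state/sim.rds")
loci <- readRDS("scratch/state/loci.rds")
st <- readRDS("scratch/state/catalog.rds")

confirmed <- Filter(function(l) l$confidence == "confirmed", loci)
homologous <- find_homologous_loci(confirmed, st$catalog$records)
message(sprintf("%d homologous locus groups (%d with >= 2 strains)",
                length(homologous), sum(lengths(homologous) >= 2)))

# the study's subclade assignment (two pairs within the four-strain clade)
groups <- list(subclade1 = sim$truth$clade$subclade1,
               subclade2 = sim$truth$clade$subclade2)
wanted <- sort(unlist(groups))
lid_strain <- setNames(vapply(confirmed, function(l) l$strain_id, ""),
                       vapply(confirmed, function(l) l$locus_id, ""))
cand <- Filter(function(g) all(wanted %in% lid_strain[g]), homologous)
pick <- function(g) { g <- g[lid_strain[g] %in% wanted]; g[!duplicated(lid_strain[g])] }
backbone <- vapply(cand, function(g) {
  toks <- lapply(pick(g), function(id)
    unique(st$catalog$records$canonical[st$catalog$records$locus_id == id]))
  length(Reduce(intersect, toks))
}, 0L)
grp <- pick(cand[[which.max(backbone)]])
sel <- Filter(function(l) l$locus_id %in% grp, confirmed)
aln <- align_token_arrays(token_arrays(sel, st$catalog$records))
blocks <- group_specific_blocks(aln, groups)
variants <- find_spacer_variants(st$catalog, sim$metadata)
saveRDS(list(alignment = aln, blocks = blocks, variants = variants),
        "scratch/state/compare.rds")

aln_df <- as.data.frame(aln$alignment)
aln_df <- cbind(locus_id = rownames(aln$alignment), aln_df)
write.table(aln_df, "results/clade_alignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(blocks, "results/clade_blocks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
vrows <- do.call(rbind, lapply(seq_along(variants), function(i) {
  cbind(group = i, length = variants[[i]]$length, variants[[i]]$members)
}))
if (!is.null(vrows)) {
  write.table(vrows, "results/spacer_variants.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}

message(sprintf("clade alignment: %d arrays, %d columns (%d shared); %d subclade-specific blocks",
                nrow(aln$alignment), ncol(aln$alignment), aln$shared_columns,
                nrow(blocks)))
for (v in variants) {
  message(sprintf("variant group: %d variants of a conserved %d-nt spacer, %d polymorphic sites",
                  v$n_variants, v$length, length(v$polymorphic_positions)))
}
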