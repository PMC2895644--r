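#!/usr/bin/env Rscript
# Stage 2: assign every read one of the seven categories by the fixed
# hierarchy (exon > intronic repeat > intron > intergenic repeat > mito >
# ncRNA > intergenic) and summarise transcriptome composition per sample,
# in read counts and in covered nucleotides.

suppressPackageStartupMessages(library(htrtools))
seed <- 1L
dir.create("results", showWarnings = FALSE)
inp <- pipeline_inputs(simulation_config(seed = seed))

rows <- list()
for (sn in names(inp$reads)) {
  cs <- composition_summary(inp$reads[[sn]], inp$annot, mode = "reads")
  rows[[sn]] <- cbind(sample = sn, mode = "reads", as.data.frame(cs))
}
cs_nt <- composition_summary(inp$reads[[1]], inp$annot,
                             mode = "covered_nucleotides")
rows$nt <- cbind(sample = names(inp$reads)[1], mode = "covered_nt",
                 as.data.frame(cs_nt))
comp <- do.call(rbind, rows)
write.table(comp, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Mean read proportions across samples (vs genome fraction):\n")
agg <- aggregate(proportion ~ category, comp[comp$mode == "reads", ], mean)
agg$genome_fraction <- cs_nt$genome_fraction[
  match(agg$category, cs_nt$category)]
print(agg[order(-agg$proportion), ], row.names = FALSE)

bias <- repeat_assignment_bias(inp$reads[[1]], inp$annot)
cat(sprintf("\n%.1f%% of repeat-assigned reads are not fully inside repeat
elements (the hierarchy's annotation bias bound).\n",
            100 * bias$fraction_partial))
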