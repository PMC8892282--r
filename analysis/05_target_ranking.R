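#!/usr/bin/env Rscript
# Endocytome target prioritization: overlap of surface and endocytosed
# identities, abundance ranking of the shared set in each fraction,
# median-split quadrant classification, and the prioritized HIGH_HIGH list.

library(surfaceomics)

exp_dir <- "results/experiment"
out <- "results/targets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

full <- read_abundance_table(file.path(exp_dir, "normalized.tsv"),
                             file.path(exp_dir, "meta.tsv"))
classifier <- read_classifier(file.path(exp_dir, "panel_classifier.tsv"))
norm <- filter_to_classifier(full, classifier)$retained
m <- norm$meta
mean_ab <- function(fr) {
  rowMeans(norm$values[, m$condition == "THREE_D" & m$fraction == fr,
                       drop = FALSE])
}
ab_s <- mean_ab("SURFACE")
ab_e <- mean_ab("ENDOCYTOSED")
ov <- overlap_partition(names(ab_s), names(ab_e))
cat(sprintf("identities: %d shared, %d surface-only, %d endocytosed-only\n",
            length(ov$shared), length(ov$surface_only),
            length(ov$endocytosed_only)))

ranked <- quadrant_classify(rank_abundances(ov$shared, ab_s, ab_e))
write.table(ranked, file.path(out, "ranked_targets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("quadrant sizes:\n")
print(table(ranked$quadrant))

prio <- prioritize_targets(ranked, top_k = 20)
write.table(prio, file.path(out, "prioritized_targets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top candidate: %s (surface rank %d, endocytome rank %d of %d)\n",
            prio$accession[1], prio$surface_rank[1], prio$endo_rank[1],
            nrow(ranked)))
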