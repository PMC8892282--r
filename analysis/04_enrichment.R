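#!/usr/bin/env Rscript
# Enrichment analyses: (i) classifier-membership enrichment in a
# biotinylated-vs-control style ranking (preranked weighted KS with
# label-permutation p), and (ii) hypergeometric overrepresentation of
# synthetic pathways among the up-regulated proteins.

library(surfaceomics)

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(20260104)

# (i) classifier members score higher in a labeled sample than background
n_bg <- 1000
ids <- sprintf("R%04d", seq_len(n_bg))
members <- sample(ids, 120)
scores <- rnorm(n_bg) + ifelse(ids %in% members, 1.5, 0)
res <- preranked_gsea(ranked_list(ids, scores), members,
                      weight_exponent = 1, n_perm = 1000, seed = 20260105)
print(res)
jsonlite::write_json(list(es = res$es, p_perm = res$p_perm,
                          n_perm = res$n_perm),
                     file.path(out, "classifier_gsea.json"),
                     auto_unbox = TRUE)

# (ii) pathway overrepresentation among the up-regulated set
venn <- jsonlite::read_json("results/dep/venn_counts.json")
dep <- read.delim("results/dep/dep_surface.tsv")
universe <- dep$accession
up <- dep$accession[dep$partition != "none"]
# synthetic pathways: one enriched in the up-set, two background draws
pathways <- list(
  adhesion_like = unique(c(sample(up, min(30, length(up))),
                           sample(universe, 20))),
  background_a = sample(universe, 40),
  background_b = sample(universe, 25))
write_gmt(pathways, file.path(out, "pathways.gmt"))
ora <- overrepresentation(up, read_gmt(file.path(out, "pathways.gmt")),
                          universe)
write.table(ora, file.path(out, "overrepresentation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ora, row.names = FALSE)
cat(sprintf("top pathway '%s': overlap %d/%d, p = %.3g, q = %.3g\n",
            ora$pathway_id[1], ora$overlap_k[1], ora$pathway_size_K[1],
            ora$p_hyper[1], ora$q_bh[1]))
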