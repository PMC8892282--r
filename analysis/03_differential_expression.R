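#!/usr/bin/env Rscript
# Differential expression of the normalized experiment: per-fraction Welch
# tests on the 3D-vs-2D contrast, the inclusive >= 0.5 log2 FC
# up-regulation partition, and the recount against the planted truth.

library(surfaceomics)

exp_dir <- "results/experiment"
out <- "results/dep"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

norm <- read_abundance_table(file.path(exp_dir, "normalized.tsv"),
                             file.path(exp_dir, "meta.tsv"))
classifier <- read_classifier(file.path(exp_dir, "panel_classifier.tsv"))
flt <- filter_to_classifier(norm, classifier)
cat(sprintf("classifier filtering: %d of %d quantified proteins retained\n",
            flt$report$n_retained, flt$report$n_input))
surf <- flt$retained
m <- surf$meta
dep_frac <- function(fr) {
  dep_test(surf, m$condition == "THREE_D" & m$fraction == fr,
           m$condition == "TWO_D" & m$fraction == fr)
}
dep_s <- dep_frac("SURFACE")
dep_e <- dep_frac("ENDOCYTOSED")
part <- upregulated_partition(setNames(dep_s$log2fc, dep_s$accession),
                              setNames(dep_e$log2fc, dep_e$accession),
                              cutoff = 0.5)
write_dep_table(dep_s, file.path(out, "dep_surface.tsv"), part)
write_dep_table(dep_e, file.path(out, "dep_endocytosed.tsv"), part)
jsonlite::write_json(list(surface_only = length(part$surface_only),
                          both = length(part$both),
                          endocytosed_only = length(part$endocytosed_only)),
                     file.path(out, "venn_counts.json"), auto_unbox = TRUE)

cat(sprintf("up-regulated (>= %.1f log2 FC): %d surface-only, %d both, %d endocytosed-only\n",
            part$cutoff, length(part$surface_only), length(part$both),
            length(part$endocytosed_only)))

truth <- read.delim(file.path(exp_dir, "planted_truth.tsv"))
truth_s <- unique(truth$accession[truth$fraction == "SURFACE"])
truth_e <- unique(truth$accession[truth$fraction == "ENDOCYTOSED"])
cat(sprintf("planted-truth agreement: surface-only %s, both %s, endocytosed-only %s\n",
            setequal(part$surface_only, setdiff(truth_s, truth_e)),
            setequal(part$both, intersect(truth_s, truth_e)),
            setequal(part$endocytosed_only, setdiff(truth_e, truth_s))))
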