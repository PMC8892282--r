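# End-to-end profiling pipeline: preprocess -> classifier filter -> DEP ->
# up-regulation partition -> enrichment -> overlap/rank/prioritize, driven
# by a single configuration with one global seed fanned out to named
# substreams.

#' Assemble a run configuration
#'
#' @param abundance,metadata Paths to the abundance and metadata TSVs.
#' @param classifier Path to a classifier TSV (see [write_classifier()]).
#' @param contrast Length-2 character vector of sample selectors
#'   (`"column:VALUE"`), test group first (e.g.
#'   `c("condition:THREE_D", "condition:TWO_D")`).
#' @param surface_fraction,endo_fraction Fraction labels used to split the
#'   contrast by fraction; defaults `"SURFACE"` and `"ENDOCYTOSED"`.
#' @param cutoff Inclusive log2 fold-change up-regulation cutoff; default 0.5.
#' @param weight_exponent,n_perm Enrichment-score weighting and permutation
#'   count; defaults 1 and 1000.
#' @param top_k Prioritized-target truncation (NULL = all).
#' @param seed Global seed; substreams (imputation, permutations) are derived
#'   from it.
#' @param out_dir Output directory for [write_report()].
#' @param zero_is_missing Abundance dialect flag.
#' @return A `run_config` list, validated for file existence.
#' @export
run_config <- function(abundance, metadata, classifier,
                       contrast = c("condition:THREE_D", "condition:TWO_D"),
                       surface_fraction = "SURFACE",
                       endo_fraction = "ENDOCYTOSED",
                       cutoff = 0.5, weight_exponent = 1, n_perm = 1000,
                       top_k = NULL, seed = 1L, out_dir = NULL,
                       zero_is_missing = FALSE) {
  stopifnot(cutoff > 0, length(contrast) == 2)
  cfg <- list(abundance = abundance, metadata = metadata,
              classifier = classifier, contrast = contrast,
              surface_fraction = surface_fraction,
              endo_fraction = endo_fraction, cutoff = cutoff,
              weight_exponent = weight_exponent, n_perm = n_perm,
              top_k = top_k, seed = as.integer(seed), out_dir = out_dir,
              zero_is_missing = isTRUE(zero_is_missing))
  for (f in c("abundance", "metadata", "classifier")) {
    if (!file.exists(cfg[[f]])) {
      stop("run_config validation: ", f, " file not found: ", cfg[[f]])
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Derived substream seeds, kept below 2^31 (double arithmetic avoids
# 32-bit overflow for large user seeds).
substream_seed <- function(seed, stream) {
  offs <- c(impute = 101, gsea = 211, simulate = 307)
  as.integer((as.numeric(seed) * 1000 + offs[[stream]]) %%
               .Machine$integer.max)
}

#' Run the full surfaceome/endocytome profile
#'
#' Executes preprocessing (imputation + normalization), classifier filtering,
#' per-fraction differential expression over the configured contrast, the
#' up-regulation partition, classifier gene-set enrichment of each fraction's
#' ranking, the surface/endocytome overlap partition, abundance ranking,
#' quadrant classification and target prioritization. Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param cfg A `run_config`.
#' @return A `profile_bundle` list: filter_report, dep (per fraction),
#'   partition, enrichment (per fraction), overlap, ranked_targets,
#'   prioritized, preprocessed matrix, and the config.
#' @export
run_profile <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  classifier <- read_classifier(cfg$classifier)
  am <- read_abundance_table(cfg$abundance, cfg$metadata,
                             zero_is_missing = cfg$zero_is_missing)
  params <- preprocess_params(seed = substream_seed(cfg$seed, "impute"))
  norm <- preprocess(am, params)
  flt <- filter_to_classifier(norm, classifier)
  surf <- flt$retained
  frac <- surf$meta$fraction
  sel <- function(contrast_side, fraction) {
    parts <- strsplit(contrast_side, ":", fixed = TRUE)[[1]]
    surf$meta[[parts[1]]] == parts[2] & frac == fraction
  }
  run_frac <- function(fraction) {
    a <- sel(cfg$contrast[1], fraction)
    b <- sel(cfg$contrast[2], fraction)
    if (!any(a) || !any(b)) {
      stop("stage dep: contrast group empty for fraction ", fraction)
    }
    dep_test(surf, a, b)
  }
  dep_s <- run_frac(cfg$surface_fraction)
  dep_e <- run_frac(cfg$endo_fraction)
  part <- upregulated_partition(
    stats::setNames(dep_s$log2fc, dep_s$accession),
    stats::setNames(dep_e$log2fc, dep_e$accession), cfg$cutoff)
  # enrichment of the classifier set within each fraction's full (unfiltered)
  # abundance ranking of the test condition
  gseed <- substream_seed(cfg$seed, "gsea")
  enrich_frac <- function(fraction) {
    parts <- strsplit(cfg$contrast[1], ":", fixed = TRUE)[[1]]
    cols <- which(am$meta[[parts[1]]] == parts[2] &
                    am$meta$fraction == fraction)
    scores <- rowMeans(log2(norm$values[, cols, drop = FALSE]))
    preranked_gsea(ranked_list(rownames(norm$values), scores),
                   classifier$entries$accession,
                   weight_exponent = cfg$weight_exponent,
                   n_perm = cfg$n_perm, seed = gseed)
  }
  enr_s <- enrich_frac(cfg$surface_fraction)
  enr_e <- enrich_frac(cfg$endo_fraction)
  # overlap/ranking over mean abundance per fraction in the test condition
  mean_ab <- function(fraction) {
    cols <- sel(cfg$contrast[1], fraction)
    rowMeans(surf$values[, cols, drop = FALSE])
  }
  ab_s <- mean_ab(cfg$surface_fraction)
  ab_e <- mean_ab(cfg$endo_fraction)
  ov <- overlap_partition(names(ab_s), names(ab_e))
  ranked <- quadrant_classify(rank_abundances(ov$shared, ab_s, ab_e))
  prio <- prioritize_targets(ranked, cfg$top_k)
  structure(list(filter_report = flt$report,
                 dep = list(surface = dep_s, endocytosed = dep_e),
                 partition = part,
                 enrichment = list(surface = enr_s, endocytosed = enr_e),
                 overlap = ov, ranked_targets = ranked, prioritized = prio,
                 preprocessed = norm, config = cfg),
            class = "profile_bundle")
}

#' Write a profile bundle to disk
#'
#' Writes the documented artifact set with stable names (DEP tables, Venn
#' counts, filter and enrichment JSON, ranked and prioritized target TSVs, a
#' human-readable summary, and a manifest with input MD5 hashes, the seed and
#' the package version).
#'
#' @param bundle A `profile_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  p <- function(...) file.path(out_dir, ...)
  write_dep_table(bundle$dep$surface, p("dep_surface.tsv"), bundle$partition)
  write_dep_table(bundle$dep$endocytosed, p("dep_endocytosed.tsv"),
                  bundle$partition)
  jsonlite::write_json(
    list(surface_only = length(bundle$partition$surface_only),
         both = length(bundle$partition$both),
         endocytosed_only = length(bundle$partition$endocytosed_only),
         cutoff = bundle$partition$cutoff),
    p("venn_counts.json"), auto_unbox = TRUE, digits = NA)
  write_filter_report(bundle$filter_report, p("filter_report.json"))
  jsonlite::write_json(
    lapply(bundle$enrichment, function(e)
      list(es = e$es, p_perm = e$p_perm, n_perm = e$n_perm)),
    p("enrichment.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(bundle$overlap, length), p("overlap_counts.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.table(bundle$ranked_targets, p("ranked_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$prioritized, p("prioritized_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("surfaceomics")),
    inputs = lapply(
      stats::setNames(c(cfg$abundance, cfg$metadata, cfg$classifier),
                      c("abundance", "metadata", "classifier")),
      function(f) list(path = f, md5 = unname(tools::md5sum(f)))),
    cutoff = cfg$cutoff, contrast = cfg$contrast)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  summary_lines <- c(
    "surfaceome/endocytome profile summary",
    sprintf("identities: %d input, %d classifier members",
            bundle$filter_report$n_input, bundle$filter_report$n_retained),
    sprintf("up-regulated (log2fc >= %.2g): %d surface-only, %d both, %d endocytosed-only",
            bundle$partition$cutoff, length(bundle$partition$surface_only),
            length(bundle$partition$both),
            length(bundle$partition$endocytosed_only)),
    sprintf("overlap: %d shared, %d surface-only, %d endocytosed-only",
            length(bundle$overlap$shared), length(bundle$overlap$surface_only),
            length(bundle$overlap$endocytosed_only)),
    sprintf("prioritized HIGH_HIGH targets: %d", nrow(bundle$prioritized)))
  writeLines(summary_lines, p("summary.txt"))
  files <- c("dep_surface.tsv", "dep_endocytosed.tsv", "venn_counts.json",
             "filter_report.json", "enrichment.json", "overlap_counts.json",
             "ranked_targets.tsv", "prioritized_targets.tsv", "manifest.json",
             "summary.txt")
  invisible(file.path(out_dir, files))
}
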