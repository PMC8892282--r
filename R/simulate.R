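# Synthetic-data generators: annotation-source fixtures for classifier
# construction and log-normal abundance experiments with planted log2
# effects and intensity-dependent (MNAR) missingness. Every generator is a
# pure function of its arguments and the seed, and returns the ground truth
# needed to score the downstream stages.

#' Default annotation-source sizes
#'
#' Record counts per source emulating a realistic nine-source surfaceome
#' merge: a 2,886-protein predictor set, GO plasma membrane (5,196), GO cell
#' surface (935), GO external side of plasma membrane (437), and reviewed
#' GPI-anchored (939), single-pass (2,356), multipass (2,819), cell membrane
#' (3,724) and extracellular-domain (2,726) exports.
#'
#' @return Named integer vector over [source_tags()].
#' @export
default_source_sizes <- function() {
  stats::setNames(c(2886L, 5196L, 935L, 437L, 939L, 2356L, 2819L, 3724L,
                    2726L), source_tags())
}

syn_acc <- function(i) sprintf("SYN%05d", i)

# Plant per-protein topology evidence realizing the given categories.
plant_topology <- function(categories, seed_offset = 0L) {
  n <- length(categories)
  tm <- integer(n); gpi <- logical(n)
  tm[categories == "SINGLE_PASS"] <- 1L
  multi <- categories == "MULTIPASS"
  tm[multi] <- sample(2:12, sum(multi), replace = TRUE)
  gpi[categories == "GPI"] <- TRUE
  list(tm_count = tm, gpi_flag = gpi)
}

#' Generate annotation-source fixtures with a known ground-truth classifier
#'
#' Builds a synthetic universe in which the final classifier is the predictor
#' set plus the curated additions. Non-predictor sources draw an
#' `overlap_fraction` of their records from the predictor set and the rest
#' from a noise pool of plasma-membrane false positives; every noise
#' accession that reaches a source is listed as a curation exclusion, and
#' the additions enter only through the curation list, so
#' `build_classifier(catalogs, curation, always_keep = "predictor")`
#' reproduces the ground truth exactly.
#'
#' @param sizes Named integer vector of per-source record counts; default
#'   [default_source_sizes()].
#' @param overlap_fraction Fraction of each non-predictor source drawn from
#'   the predictor set; default 0.5.
#' @param n_curated_additions Number of curated additions; default 431.
#' @param category_targets Optional named counts (GPI, SINGLE_PASS,
#'   MULTIPASS, OTHER) that must sum to the ground-truth total; topology
#'   evidence is planted to force exactly these counts. Default: categories
#'   sampled with probabilities proportional to a 140/1316/1750/116
#'   composition.
#' @param n_noise Size of the false-positive noise pool; default 8000.
#' @param seed Integer seed.
#' @return List with `catalogs` (nine `source_catalog`s), `curation`
#'   (a `curation_list`), `always_keep` (the predictor accessions), and
#'   `truth` (the expected `surfme_classifier`).
#' @export
simulate_annotation_sources <- function(sizes = default_source_sizes(),
                                        overlap_fraction = 0.5,
                                        n_curated_additions = 431L,
                                        category_targets = NULL,
                                        n_noise = 8000L, seed = 1L) {
  stopifnot(all(source_tags() %in% names(sizes)), all(sizes >= 0),
            overlap_fraction >= 0, overlap_fraction <= 1)
  set.seed(seed)
  n_pred <- as.integer(sizes[["predictor"]])
  n_add <- as.integer(n_curated_additions)
  n_truth <- n_pred + n_add
  # universe: truth proteins first, then the noise pool
  n_univ <- n_truth + n_noise
  acc <- syn_acc(seq_len(n_univ))
  sym <- sprintf("GENE%05d", seq_len(n_univ))
  if (is.null(category_targets)) {
    cats <- sample(surfme_categories(), n_truth, replace = TRUE,
                   prob = c(140, 1316, 1750, 116) / 3322)
  } else {
    stopifnot(setequal(names(category_targets), surfme_categories()))
    if (sum(category_targets) != n_truth) {
      stop("category_targets must sum to the ground-truth total (",
           n_truth, ")")
    }
    cats <- sample(rep(surfme_categories(),
                       times = category_targets[surfme_categories()]))
  }
  noise_cats <- sample(surfme_categories(), n_noise, replace = TRUE)
  topo <- plant_topology(c(cats, noise_cats))
  univ <- data.frame(accession = acc, symbol = sym,
                     tm_count = topo$tm_count, gpi_flag = topo$gpi_flag,
                     reviewed = TRUE, stringsAsFactors = FALSE)
  pred_idx <- seq_len(n_pred)
  add_idx <- n_pred + seq_len(n_add)
  noise_idx <- n_truth + seq_len(n_noise)

  catalogs <- vector("list", length(source_tags()))
  names(catalogs) <- source_tags()
  catalogs[["predictor"]] <- new_source_catalog("predictor",
                                                univ[pred_idx, , drop = FALSE])
  used_noise <- integer(0)
  for (tag in setdiff(source_tags(), "predictor")) {
    sz <- as.integer(sizes[[tag]])
    k_true <- min(round(sz * overlap_fraction), n_pred)
    k_noise <- sz - k_true
    if (k_noise > n_noise) {
      stop("source ", tag, " needs ", k_noise,
           " noise records but the pool has only ", n_noise)
    }
    rows <- c(sample(pred_idx, k_true), sample(noise_idx, k_noise))
    catalogs[[tag]] <- new_source_catalog(tag, univ[rows, , drop = FALSE])
    used_noise <- union(used_noise, intersect(rows, noise_idx))
  }
  curation <- new_curation_list(
    exclusions = data.frame(accession = univ$accession[sort(used_noise)],
                            reason = "no-extracellular-evidence",
                            stringsAsFactors = FALSE),
    additions = univ[add_idx, c("accession", "symbol", "tm_count",
                                "gpi_flag"), drop = FALSE]
  )
  truth_entries <- data.frame(
    accession = univ$accession[c(pred_idx, add_idx)],
    symbol = univ$symbol[c(pred_idx, add_idx)],
    category = cats, stringsAsFactors = FALSE)
  truth_entries$provenance <- rep(list(NA_character_), nrow(truth_entries))
  truth_entries <- truth_entries[order(truth_entries$accession), , drop = FALSE]
  rownames(truth_entries) <- NULL
  list(catalogs = catalogs, curation = curation,
       always_keep = univ$accession[pred_idx],
       truth = new_classifier(truth_entries, version_label = "synthetic"))
}

#' Write annotation fixtures to a directory
#'
#' Writes one TSV per source (`<tag>.tsv`) and `curation.csv` in the dialects
#' read by [load_source_catalog()] and [read_curation()].
#'
#' @param fixture Result of [simulate_annotation_sources()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tag in names(fixture$catalogs)) {
    utils::write.table(fixture$catalogs[[tag]]$records,
                       file.path(dir, paste0(tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cur <- fixture$curation
  excl <- data.frame(accession = cur$exclusions$accession, action = "exclude",
                     reason = cur$exclusions$reason, symbol = "",
                     tm_count = "", gpi_flag = "", stringsAsFactors = FALSE)
  add <- data.frame(accession = cur$additions$accession, action = "add",
                    reason = "curated-addition",
                    symbol = cur$additions$symbol,
                    tm_count = cur$additions$tm_count,
                    gpi_flag = cur$additions$gpi_flag,
                    stringsAsFactors = FALSE)
  utils::write.csv(rbind(excl, add), file.path(dir, "curation.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a log-normal abundance experiment with planted effects
#'
#' Per-protein log2 intensities are drawn as
#' `baseline_p + delta(p, sample) + Normal(0, base_log2_sd)`, with protein
#' baselines `base_log2_mean + Normal(0, protein_log2_sd)` giving a realistic
#' dynamic range. Planted log2 effects are applied to designated
#' condition/fraction groups. Cells go missing with probability
#' `plogis(missing_intercept - missing_slope * log2_intensity)` (lower
#' abundance, more dropout); values are exported on the linear scale.
#'
#' @param n_proteins Number of proteins; default 500.
#' @param conditions,fractions Condition and fraction levels to emit;
#'   defaults `c("TWO_D","THREE_D")` and `c("SURFACE","ENDOCYTOSED")`.
#' @param n_replicates Replicates per condition x fraction; default 3.
#' @param base_log2_mean Global mean log2 intensity; default 20.
#' @param base_log2_sd Within-group replicate SD in log2 units; default 0.3.
#' @param protein_log2_sd SD of protein baselines; default 2.
#' @param planted_effects data.frame(accession, condition, fraction, delta)
#'   of log2 shifts, or NULL. `fraction = "*"` applies to every fraction.
#' @param partition_targets Optional named counts (surface_only, both,
#'   endocytosed_only): builds `planted_effects` that up-regulate the first
#'   proteins in the second condition by `partition_delta` in the surface,
#'   both, or endocytosed fractions respectively.
#' @param partition_delta Planted log2 effect used with `partition_targets`;
#'   default 1.5.
#' @param missing_slope,missing_intercept Logistic MNAR dropout model on the
#'   log2 scale; the defaults (`slope = 0.75`, intercept placing 50% dropout
#'   4 log2 units below the global mean) give sparse, intensity-dependent
#'   missingness. `missing_intercept = -Inf` disables missingness.
#' @param seed Integer seed.
#' @return List with `matrix` (an `abundance_matrix`) and `truth`
#'   (data.frame accession, condition, fraction, delta of planted effects;
#'   empty when none).
#' @export
simulate_abundance_experiment <- function(n_proteins = 500L,
                                          conditions = c("TWO_D", "THREE_D"),
                                          fractions = c("SURFACE", "ENDOCYTOSED"),
                                          n_replicates = 3L,
                                          base_log2_mean = 20,
                                          base_log2_sd = 0.3,
                                          protein_log2_sd = 2,
                                          planted_effects = NULL,
                                          partition_targets = NULL,
                                          partition_delta = 1.5,
                                          missing_slope = 0.75,
                                          missing_intercept = NULL,
                                          seed = 1L) {
  stopifnot(n_proteins > 0, n_replicates >= 1)
  set.seed(seed)
  if (is.null(missing_intercept)) {
    missing_intercept <- missing_slope * (base_log2_mean - 4)
  }
  acc <- syn_acc(seq_len(n_proteins))
  if (!is.null(partition_targets)) {
    stopifnot(length(conditions) >= 2, length(fractions) >= 2,
              all(c("surface_only", "both", "endocytosed_only") %in%
                    names(partition_targets)))
    ns <- partition_targets[["surface_only"]]
    nb <- partition_targets[["both"]]
    ne <- partition_targets[["endocytosed_only"]]
    if (ns + nb + ne > n_proteins) {
      stop("partition targets exceed n_proteins")
    }
    cond_up <- conditions[2]
    mk <- function(ids, fracs) {
      expand.grid(accession = ids, condition = cond_up, fraction = fracs,
                  stringsAsFactors = FALSE)
    }
    planted_effects <- rbind(
      mk(acc[seq_len(ns)], fractions[1]),
      mk(acc[ns + seq_len(nb)], fractions),
      mk(acc[ns + nb + seq_len(ne)], fractions[2]))
    planted_effects$delta <- partition_delta
  }
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      fraction = fractions, condition = conditions,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("condition", "fraction", "replicate")]
  meta$sample_id <- sprintf("%s_%s_r%d", meta$condition, meta$fraction,
                            meta$replicate)
  meta$subject <- "synthetic"
  meta <- meta[, c("sample_id", "condition", "fraction", "subject",
                   "replicate")]
  baseline <- base_log2_mean + stats::rnorm(n_proteins, 0, protein_log2_sd)
  shift <- matrix(0, n_proteins, nrow(meta),
                  dimnames = list(acc, meta$sample_id))
  if (!is.null(planted_effects) && nrow(planted_effects)) {
    for (r in seq_len(nrow(planted_effects))) {
      pe <- planted_effects[r, ]
      cols <- meta$condition == pe$condition &
        (pe$fraction == "*" | meta$fraction == pe$fraction)
      shift[pe$accession, cols] <- shift[pe$accession, cols] + pe$delta
    }
  }
  log2_vals <- baseline + shift +
    matrix(stats::rnorm(n_proteins * nrow(meta), 0, base_log2_sd),
           n_proteins, nrow(meta))
  p_miss <- stats::plogis(missing_intercept - missing_slope * log2_vals)
  vals <- 2^log2_vals
  drop <- matrix(stats::runif(length(vals)) < p_miss, nrow(vals))
  vals[drop] <- NA_real_
  truth <- if (is.null(planted_effects)) {
    data.frame(accession = character(0), condition = character(0),
               fraction = character(0), delta = numeric(0))
  } else planted_effects
  list(matrix = new_abundance_matrix(vals, meta), truth = truth)
}

#' Generate a synthetic patient cohort with per-patient hotspot proteins
#'
#' One sample per patient over a shared protein panel; each patient
#' overexpresses a distinct planted hotspot subset by `hotspot_delta` log2
#' units, emulating heterogeneous relative surfaceome abundance across
#' tumors.
#'
#' @param n_patients Number of patients; default 10.
#' @param n_proteins Panel size; default 300.
#' @param hotspot_size Hotspot proteins per patient; default 20.
#' @param hotspot_delta Planted log2 overexpression; default 2.
#' @param base_log2_mean,base_log2_sd,protein_log2_sd As in
#'   [simulate_abundance_experiment()].
#' @param seed Integer seed.
#' @return List with `matrix` (an `abundance_matrix`, one sample per
#'   patient, no missingness) and `hotspots` (named list patient ->
#'   accessions).
#' @export
simulate_patient_cohort <- function(n_patients = 10L, n_proteins = 300L,
                                    hotspot_size = 20L, hotspot_delta = 2,
                                    base_log2_mean = 20, base_log2_sd = 0.3,
                                    protein_log2_sd = 1.5, seed = 1L) {
  stopifnot(n_patients >= 1, hotspot_size * n_patients <= n_proteins)
  set.seed(seed)
  acc <- syn_acc(seq_len(n_proteins))
  patients <- sprintf("PAT%02d", seq_len(n_patients))
  pool <- sample(acc)
  hotspots <- split(pool[seq_len(hotspot_size * n_patients)],
                    rep(patients, each = hotspot_size))
  meta <- data.frame(sample_id = patients, condition = "PATIENT",
                     fraction = "SURFACE", subject = patients,
                     replicate = 1L, stringsAsFactors = FALSE)
  baseline <- base_log2_mean + stats::rnorm(n_proteins, 0, protein_log2_sd)
  log2_vals <- baseline +
    matrix(stats::rnorm(n_proteins * n_patients, 0, base_log2_sd),
           n_proteins, n_patients, dimnames = list(acc, patients))
  for (p in patients) {
    log2_vals[hotspots[[p]], p] <- log2_vals[hotspots[[p]], p] + hotspot_delta
  }
  list(matrix = new_abundance_matrix(2^log2_vals, meta),
       hotspots = hotspots[patients])
}
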