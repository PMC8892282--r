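# Synthetic-data generators: determinism, planted ground truth, MNAR
# missingness structure.

small_sizes <- setNames(c(40, 50, 15, 10, 15, 30, 30, 40, 30), source_tags())

test_that("annotation fixtures are deterministic and rebuild their ground truth", {
  fix1 <- simulate_annotation_sources(small_sizes, n_curated_additions = 8,
                                      n_noise = 150, seed = 61)
  fix2 <- simulate_annotation_sources(small_sizes, n_curated_additions = 8,
                                      n_noise = 150, seed = 61)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_annotation_fixture(fix1, d1)
  write_annotation_fixture(fix2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  # the built classifier equals the recorded ground truth
  catalogs <- lapply(source_tags(), function(tg)
    load_source_catalog(file.path(d1, paste0(tg, ".tsv")), tg))
  cl <- build_classifier(catalogs, read_curation(file.path(d1, "curation.csv")),
                         always_keep = "predictor")
  expect_identical(cl$entries$accession, fix1$truth$entries$accession)
  expect_identical(cl$entries$category, fix1$truth$entries$category)
  expect_equal(cl$summary$total, 40 + 8)
})

test_that("category targets force the classifier composition exactly", {
  targets <- c(GPI = 5L, SINGLE_PASS = 20L, MULTIPASS = 18L, OTHER = 5L)
  fix <- simulate_annotation_sources(small_sizes, n_curated_additions = 8,
                                     category_targets = targets,
                                     n_noise = 150, seed = 62)
  cl <- build_classifier(fix$catalogs, fix$curation,
                         always_keep = "predictor")
  expect_equal(unlist(cl$summary[names(targets)]), targets)

  bad <- c(GPI = 5L, SINGLE_PASS = 20L, MULTIPASS = 18L, OTHER = 6L)
  expect_error(simulate_annotation_sources(small_sizes,
                                           n_curated_additions = 8,
                                           category_targets = bad,
                                           n_noise = 150, seed = 62),
               "sum")
})

test_that("abundance experiments are seeded pure functions with MNAR dropout", {
  a <- simulate_abundance_experiment(n_proteins = 60, seed = 63)
  b <- simulate_abundance_experiment(n_proteins = 60, seed = 63)
  expect_identical(a$matrix$values, b$matrix$values)

  none <- simulate_abundance_experiment(n_proteins = 60,
                                        missing_intercept = -Inf, seed = 63)
  expect_false(anyNA(none$matrix$values))

  # dropout increases as the intensity scale decreases, model held fixed
  rate_at <- function(mu) {
    sim <- simulate_abundance_experiment(n_proteins = 300,
                                         base_log2_mean = mu,
                                         missing_slope = 0.75,
                                         missing_intercept = 0.75 * 16,
                                         seed = 64)
    mean(is.na(sim$matrix$values))
  }
  expect_gt(rate_at(18), rate_at(20))
  expect_gt(rate_at(20), rate_at(24))
})

test_that("partition targets plant an exactly recoverable up-regulation truth", {
  sim <- simulate_abundance_experiment(
    n_proteins = 60, n_replicates = 3, base_log2_sd = 0.1,
    partition_targets = c(surface_only = 3, both = 4, endocytosed_only = 5),
    partition_delta = 1.5, missing_intercept = -Inf, seed = 65)
  sel <- function(fr) {
    m <- sim$matrix$meta
    list(a = m$condition == "THREE_D" & m$fraction == fr,
         b = m$condition == "TWO_D" & m$fraction == fr)
  }
  s <- sel("SURFACE"); e <- sel("ENDOCYTOSED")
  part <- upregulated_partition(
    log2_fold_change(sim$matrix, s$a, s$b),
    log2_fold_change(sim$matrix, e$a, e$b))
  expect_length(part$surface_only, 3)
  expect_length(part$both, 4)
  expect_length(part$endocytosed_only, 5)
  # and the identities match the generator's truth table
  truth_s <- unique(sim$truth$accession[sim$truth$fraction == "SURFACE"])
  truth_e <- unique(sim$truth$accession[sim$truth$fraction == "ENDOCYTOSED"])
  expect_setequal(part$surface_only, setdiff(truth_s, truth_e))
  expect_setequal(part$both, intersect(truth_s, truth_e))
  expect_setequal(part$endocytosed_only, setdiff(truth_e, truth_s))
})

test_that("patient cohorts plant recoverable hotspot subsets", {
  co <- simulate_patient_cohort(n_patients = 2, n_proteins = 60,
                                hotspot_size = 8, hotspot_delta = 3,
                                seed = 66)
  rel <- relative_abundance_to_min(co$matrix)
  for (p in names(co$hotspots)) {
    top <- rownames(rel)[order(-rel[, p])][1:8]
    expect_setequal(top, co$hotspots[[p]])
  }

  one <- simulate_patient_cohort(n_patients = 1, n_proteins = 30,
                                 hotspot_size = 5, seed = 67)
  rel1 <- relative_abundance_to_min(one$matrix)
  expect_true(all(rel1 == 0))  # single sample is every protein's minimum

  again <- simulate_patient_cohort(n_patients = 2, n_proteins = 60,
                                   hotspot_size = 8, hotspot_delta = 3,
                                   seed = 66)
  expect_identical(co$matrix$values, again$matrix$values)
  expect_identical(co$hotspots, again$hotspots)
})
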