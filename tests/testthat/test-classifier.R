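# Classifier construction: source loading, merging, curation, topology
# categorization.

test_that("loading strips isoform suffixes and deduplicates accessions", {
  path <- write_source_tsv(data.frame(accession = c("P1", "P1-2", "P2")))
  cat <- load_source_catalog(path, "predictor")
  expect_setequal(cat$records$accession, c("P1", "P2"))

  empty <- write_source_tsv(data.frame(accession = character(0)))
  expect_equal(nrow(load_source_catalog(empty, "predictor")$records), 0)

  noacc <- write_source_tsv(data.frame(id = "P1"))
  expect_error(load_source_catalog(noacc, "predictor"), "accession")
  expect_error(load_source_catalog(path, "not_a_source"))
})

test_that("merging unions accessions and reconciles topology evidence", {
  a <- new_source_catalog("predictor",
                          data.frame(accession = c("P1", "P2"),
                                     tm_count = c(1, 0),
                                     gpi_flag = c(FALSE, TRUE)))
  b <- new_source_catalog("go_plasma_membrane",
                          data.frame(accession = c("P2", "P3"),
                                     tm_count = c(4, 2)))
  m <- merge_sources(list(a, b))
  expect_equal(nrow(m), 3)
  expect_setequal(m$provenance[[match("P2", m$accession)]],
                  c("predictor", "go_plasma_membrane"))
  expect_equal(m$tm_count[match("P2", m$accession)], 4)   # max across sources
  expect_true(m$gpi_flag[match("P2", m$accession)])       # OR across sources

  both <- merge_sources(list(a, new_source_catalog("go_cell_surface",
                                                   data.frame(accession = "P1"))))
  expect_length(both$provenance[[match("P1", both$accession)]], 2)
})

test_that("merged size equals the brute-force union over random catalogs", {
  set.seed(41)
  for (rep in 1:20) {
    tags <- sample(source_tags(), sample(2:4, 1))
    cats <- lapply(tags, function(tg) {
      new_source_catalog(tg, data.frame(
        accession = sample(sprintf("P%02d", 1:100), sample(1:60, 1))))
    })
    m <- merge_sources(cats)
    union_oracle <- unique(unlist(lapply(cats, function(ct) ct$records$accession)))
    expect_setequal(m$accession, union_oracle)
    expect_true(all(lengths(m$provenance) >= 1))
    expect_true(all(unlist(m$provenance) %in% source_tags()))
  }
})

test_that("symbol conflicts resolve by source priority with a warning", {
  a <- new_source_catalog("predictor",
                          data.frame(accession = "P1", symbol = "HIGH"))
  b <- new_source_catalog("cell_membrane",
                          data.frame(accession = "P1", symbol = "LOW"))
  expect_warning(m <- merge_sources(list(b, a)), "priority")
  expect_equal(m$symbol, "HIGH")
})

test_that("curation removes exclusions, honors always-keep, inserts additions", {
  merged <- merge_sources(list(new_source_catalog(
    "predictor", data.frame(accession = c("P1", "P2", "P3")))))

  ident <- apply_curation(merged, new_curation_list())
  expect_identical(ident$accession, merged$accession)

  cur <- new_curation_list(exclusions = data.frame(accession = "P2"))
  expect_setequal(apply_curation(merged, cur)$accession, c("P1", "P3"))

  expect_message(kept <- apply_curation(merged, cur, always_keep = c("P2")),
                 "overridden")
  expect_setequal(kept$accession, c("P1", "P2", "P3"))

  add <- new_curation_list(additions = data.frame(accession = "P9",
                                                  tm_count = 1))
  out <- apply_curation(merged, add)
  expect_setequal(out$accession, c("P1", "P2", "P3", "P9"))
  expect_equal(out$provenance[[match("P9", out$accession)]],
               "curated-addition")

  clash <- new_curation_list(additions = data.frame(accession = "P1"))
  expect_warning(out2 <- apply_curation(merged, clash), "already present")
  expect_setequal(out2$accession, c("P1", "P2", "P3"))
  expect_true("curated-addition" %in%
                out2$provenance[[match("P1", out2$accession)]])

  expect_error(new_curation_list(exclusions = data.frame(accession = "P1"),
                                 additions = data.frame(accession = "P1")),
               "both excluded and added")
})

test_that("curation is monotone in entry count", {
  merged <- merge_sources(list(new_source_catalog(
    "predictor", data.frame(accession = sprintf("P%d", 1:20)))))
  base <- nrow(apply_curation(merged, new_curation_list()))
  for (i in 1:5) {
    ex <- new_curation_list(exclusions = data.frame(
      accession = sprintf("P%d", sample(20, i))))
    expect_lte(nrow(apply_curation(merged, ex)), base)
    ad <- new_curation_list(additions = data.frame(
      accession = sprintf("X%d", seq_len(i))))
    expect_gte(nrow(apply_curation(merged, ad)), base)
  }
})

test_that("categorization is total with GPI > multipass > single-pass precedence", {
  expect_equal(categorize(1, FALSE), "SINGLE_PASS")
  expect_equal(categorize(0, TRUE), "GPI")
  expect_equal(categorize(3, TRUE), "GPI")
  expect_equal(categorize(0, FALSE), "OTHER")
  expect_equal(categorize(c(2, 7), c(FALSE, FALSE)),
               c("MULTIPASS", "MULTIPASS"))
})

test_that("build_classifier composes merge, curation and categorization", {
  empty <- build_classifier(list(new_source_catalog(
    "predictor", data.frame(accession = character(0)))))
  expect_equal(empty$summary$total, 0)
  expect_equal(empty$summary$GPI + empty$summary$SINGLE_PASS +
                 empty$summary$MULTIPASS + empty$summary$OTHER, 0)

  cat <- new_source_catalog("predictor", data.frame(
    accession = c("P1", "P2", "P3"), tm_count = c(1, 3, 0),
    gpi_flag = c(FALSE, FALSE, TRUE)))
  cl <- build_classifier(list(cat))
  expect_equal(unlist(cl$summary[surfme_categories()]),
               c(GPI = 1L, SINGLE_PASS = 1L, MULTIPASS = 1L, OTHER = 0L))
  expect_equal(cl$summary$total, 3)
})

test_that("category counts always partition the total", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    cat <- new_source_catalog("predictor", data.frame(
      accession = sprintf("P%03d", sample(500, n)),
      tm_count = sample(0:5, n, replace = TRUE),
      gpi_flag = sample(c(TRUE, FALSE), n, replace = TRUE)))
    cl <- build_classifier(list(cat))
    expect_equal(cl$summary$GPI + cl$summary$SINGLE_PASS +
                   cl$summary$MULTIPASS + cl$summary$OTHER,
                 cl$summary$total)
  }
})

test_that("classifier serialization round-trips and rebuild is idempotent", {
  fix <- simulate_annotation_sources(
    sizes = setNames(c(40, 50, 15, 10, 15, 30, 30, 40, 30), source_tags()),
    n_curated_additions = 8, n_noise = 150, seed = 11)
  cl <- build_classifier(fix$catalogs, fix$curation,
                         always_keep = "predictor", version_label = "v1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classifier(cl, path)
  back <- read_classifier(path)
  expect_identical(back$entries$accession, cl$entries$accession)
  expect_identical(back$entries$category, cl$entries$category)
  expect_identical(back$summary, cl$summary)
  expect_identical(back$version_label, "v1")

  # rebuilding from the serialized entries as a single source, no curation,
  # reproduces the same entry set and categories
  rec <- data.frame(accession = back$entries$accession,
                    symbol = back$entries$symbol,
                    tm_count = ifelse(back$entries$category == "MULTIPASS", 2L,
                                      ifelse(back$entries$category == "SINGLE_PASS", 1L, 0L)),
                    gpi_flag = back$entries$category == "GPI",
                    stringsAsFactors = FALSE)
  again <- build_classifier(list(new_source_catalog("predictor", rec)))
  expect_identical(again$entries$accession, cl$entries$accession)
  expect_identical(again$entries$category, cl$entries$category)
})
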