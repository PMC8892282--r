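# Surfaceome classifier construction: merge annotation-source exports,
# apply a curation list, and assign one topology category per protein.

#' Enumerated annotation source tags
#'
#' The fixed set of nine annotation sources a surfaceome classifier is merged
#' from, in priority order: a machine-learning surfaceome predictor, three GO
#' membership terms, four reviewed UniProt topology/keyword exports, and the
#' extracellular-domain topology term. The order defines symbol-conflict
#' priority during merging.
#'
#' @return Character vector of the nine source tags, highest priority first.
#' @export
source_tags <- function() {
  c("predictor", "go_plasma_membrane", "go_cell_surface", "go_external_side",
    "gpi_anchored", "single_pass", "multipass", "cell_membrane",
    "extracellular_domain")
}

#' Topology category labels
#'
#' @return Character vector of the four mutually exclusive categories.
#' @export
surfme_categories <- function() {
  c("GPI", "SINGLE_PASS", "MULTIPASS", "OTHER")
}

# Strip a trailing isoform suffix ("-<digits>") from accessions.
strip_isoform <- function(accession) {
  sub("-[0-9]+$", "", accession)
}

#' Load one annotation-source export
#'
#' Reads a tab-delimited export with a mandatory `accession` column and
#' optional `symbol`, `tm_count`, `gpi_flag` and `reviewed` columns. Isoform
#' suffixes (trailing `-<digits>`) are stripped and duplicate accessions
#' collapsed; for duplicates the maximum `tm_count` and logical OR of
#' `gpi_flag` are retained.
#'
#' @param path Path to the TSV export.
#' @param source_tag One of [source_tags()].
#' @return A `source_catalog`: list with `source_tag` and a data.frame
#'   `records` (accession, symbol, tm_count, gpi_flag, reviewed).
#' @export
load_source_catalog <- function(path, source_tag) {
  source_tag <- match.arg(source_tag, source_tags())
  if (!file.exists(path)) stop("source export not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"accession" %in% names(df)) {
    stop("format error in ", path,
         ": missing mandatory 'accession' column; expected columns ",
         "accession[, symbol, tm_count, gpi_flag, reviewed]")
  }
  n <- nrow(df)
  rec <- data.frame(
    accession = strip_isoform(as.character(df$accession)),
    symbol    = if ("symbol" %in% names(df)) as.character(df$symbol)
                else rep(NA_character_, n),
    tm_count  = if ("tm_count" %in% names(df)) as.integer(df$tm_count)
                else rep(0L, n),
    gpi_flag  = if ("gpi_flag" %in% names(df))
      as.logical(df$gpi_flag) %in% TRUE else rep(FALSE, n),
    reviewed  = if ("reviewed" %in% names(df))
      as.logical(df$reviewed) %in% TRUE else rep(TRUE, n),
    stringsAsFactors = FALSE
  )
  rec$tm_count[is.na(rec$tm_count)] <- 0L
  new_source_catalog(source_tag, rec)
}

#' Construct a source catalog from records in memory
#'
#' @param source_tag One of [source_tags()].
#' @param records data.frame with at least an `accession` column.
#' @return A `source_catalog` with deduplicated, isoform-stripped accessions.
#' @export
new_source_catalog <- function(source_tag, records) {
  source_tag <- match.arg(source_tag, source_tags())
  stopifnot(is.data.frame(records), "accession" %in% names(records))
  rec <- records
  rec$accession <- strip_isoform(as.character(rec$accession))
  if (any(!nzchar(rec$accession))) stop("empty accession in source ", source_tag)
  if (!"symbol" %in% names(rec)) rec$symbol <- rep(NA_character_, nrow(rec))
  if (!"tm_count" %in% names(rec)) rec$tm_count <- rep(0L, nrow(rec))
  if (!"gpi_flag" %in% names(rec)) rec$gpi_flag <- rep(FALSE, nrow(rec))
  if (!"reviewed" %in% names(rec)) rec$reviewed <- rep(TRUE, nrow(rec))
  rec$tm_count <- as.integer(rec$tm_count)
  if (any(rec$tm_count < 0, na.rm = TRUE)) stop("negative tm_count in ", source_tag)
  if (anyDuplicated(rec$accession)) {
    rec <- do.call(rbind, lapply(split(rec, rec$accession), function(g) {
      data.frame(accession = g$accession[1], symbol = g$symbol[1],
                 tm_count = max(g$tm_count), gpi_flag = any(g$gpi_flag),
                 reviewed = any(g$reviewed), stringsAsFactors = FALSE)
    }))
  }
  rownames(rec) <- NULL
  structure(list(source_tag = source_tag,
                 records = rec[, c("accession", "symbol", "tm_count",
                                   "gpi_flag", "reviewed")]),
            class = "source_catalog")
}

#' @export
print.source_catalog <- function(x, ...) {
  cat("<source_catalog>", x$source_tag, "-", nrow(x$records), "records\n")
  invisible(x)
}

#' Merge annotation-source catalogs (duplicate removal, "filter A")
#'
#' Produces one record per accession with a provenance set of contributing
#' source tags. Topology evidence is reconciled across sources by the maximum
#' transmembrane-segment count and the logical OR of the GPI flag. When
#' sources disagree on the gene symbol the symbol from the highest-priority
#' source (the order of [source_tags()]) is kept and a warning is emitted.
#'
#' @param catalogs List of `source_catalog` objects.
#' @return data.frame with columns accession, symbol, tm_count, gpi_flag,
#'   reviewed, provenance (list column of source tags).
#' @export
merge_sources <- function(catalogs) {
  if (length(catalogs) < 1) stop("merge_sources requires at least one catalog")
  stopifnot(all(vapply(catalogs, inherits, logical(1), "source_catalog")))
  prio <- source_tags()
  ord <- order(match(vapply(catalogs, `[[`, character(1), "source_tag"), prio))
  catalogs <- catalogs[ord]
  long <- do.call(rbind, lapply(catalogs, function(cat) {
    r <- cat$records
    r$source_tag <- rep(cat$source_tag, nrow(r))
    r
  }))
  # rows are in source-priority order; a stable sort by accession keeps that
  # order within each accession group, so the first non-NA symbol per group
  # is the highest-priority one
  long <- long[order(long$accession), , drop = FALSE]
  grp <- factor(long$accession, levels = unique(long$accession))
  first_sym <- vapply(split(long$symbol, grp), function(s) {
    i <- which(!is.na(s))[1]
    if (is.na(i)) NA_character_ else s[i]
  }, character(1))
  n_sym <- vapply(split(long$symbol, grp),
                  function(s) length(unique(s[!is.na(s)])), integer(1))
  conflicts <- levels(grp)[n_sym > 1]
  out <- data.frame(
    accession = levels(grp),
    symbol = unname(first_sym),
    tm_count = as.integer(vapply(split(long$tm_count, grp), max, numeric(1))),
    gpi_flag = vapply(split(long$gpi_flag, grp), any, logical(1)),
    reviewed = vapply(split(long$reviewed, grp), any, logical(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$provenance <- unname(lapply(split(long$source_tag, grp), unique))
  if (length(conflicts)) {
    warning("symbol conflicts resolved by source priority for ",
            length(conflicts), " accession(s): ",
            paste(utils::head(conflicts, 5), collapse = ", "),
            if (length(conflicts) > 5) ", ..." else "")
  }
  out
}

#' Read a curation list (exclusions and additions, "filter B")
#'
#' CSV with columns `accession,action,reason,symbol,tm_count,gpi_flag` where
#' `action` is `exclude` or `add`. Exclusion reason codes are free text
#' (e.g. duplicate-false-positive, no-extracellular-evidence,
#' literature-rejected).
#'
#' @param path Path to the curation CSV.
#' @return A `curation_list`: list with data.frames `exclusions` and
#'   `additions`.
#' @export
read_curation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("accession", "action")
  if (!all(need %in% names(df))) {
    stop("curation file ", path, " must have columns accession,action")
  }
  if (!all(df$action %in% c("exclude", "add"))) {
    stop("curation action must be 'exclude' or 'add'")
  }
  new_curation_list(
    exclusions = df[df$action == "exclude",
                    intersect(c("accession", "reason"), names(df)),
                    drop = FALSE],
    additions  = df[df$action == "add", , drop = FALSE]
  )
}

#' Construct a curation list in memory
#'
#' @param exclusions data.frame with `accession` (and optional `reason`).
#' @param additions data.frame with `accession` (and optional symbol,
#'   tm_count, gpi_flag).
#' @return A `curation_list`.
#' @export
new_curation_list <- function(exclusions = NULL, additions = NULL) {
  empty <- data.frame(accession = character(0), stringsAsFactors = FALSE)
  if (is.null(exclusions)) exclusions <- empty
  if (is.null(additions)) additions <- empty
  exclusions$accession <- strip_isoform(as.character(exclusions$accession))
  additions$accession <- strip_isoform(as.character(additions$accession))
  if (!"reason" %in% names(exclusions)) {
    exclusions$reason <- rep(NA_character_, nrow(exclusions))
  }
  if (!"symbol" %in% names(additions)) {
    additions$symbol <- rep(NA_character_, nrow(additions))
  }
  if (!"tm_count" %in% names(additions)) {
    additions$tm_count <- rep(0L, nrow(additions))
  }
  if (!"gpi_flag" %in% names(additions)) {
    additions$gpi_flag <- rep(FALSE, nrow(additions))
  }
  additions$tm_count <- as.integer(additions$tm_count)
  additions$tm_count[is.na(additions$tm_count)] <- 0L
  additions$gpi_flag <- as.logical(additions$gpi_flag) %in% TRUE
  both <- intersect(exclusions$accession, additions$accession)
  if (length(both)) {
    stop("curation list has accessions both excluded and added: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  structure(list(exclusions = exclusions, additions = additions),
            class = "curation_list")
}

#' Apply a curation list to a merged record map
#'
#' Exclusions are dropped unless protected by `always_keep` (e.g. the full
#' predictor identity set is retained as true hits); overridden exclusions
#' are reported via a message. Additions are inserted with provenance
#' `"curated-addition"`; an addition colliding with an existing accession
#' keeps the existing record, merges provenance, and warns.
#'
#' @param merged data.frame from [merge_sources()].
#' @param curation A `curation_list`.
#' @param always_keep Character vector of accessions never excluded.
#' @return data.frame of the same shape as `merged`.
#' @export
apply_curation <- function(merged, curation, always_keep = character(0)) {
  stopifnot(inherits(curation, "curation_list"))
  always_keep <- strip_isoform(always_keep)
  excl <- setdiff(curation$exclusions$accession, always_keep)
  overridden <- intersect(curation$exclusions$accession, always_keep)
  if (length(overridden)) {
    message(length(overridden),
            " exclusion(s) overridden by the always-keep set")
  }
  out <- merged[!merged$accession %in% excl, , drop = FALSE]
  add <- curation$additions
  if (nrow(add)) {
    clash <- add$accession %in% out$accession
    if (any(clash)) {
      warning(sum(clash), " curated addition(s) already present; ",
              "existing records kept, provenance merged")
      idx <- match(add$accession[clash], out$accession)
      out$provenance[idx] <- lapply(out$provenance[idx],
                                    function(p) union(p, "curated-addition"))
    }
    add <- add[!clash, , drop = FALSE]
    if (nrow(add)) {
      newrec <- data.frame(accession = add$accession, symbol = add$symbol,
                           tm_count = add$tm_count, gpi_flag = add$gpi_flag,
                           reviewed = TRUE, stringsAsFactors = FALSE)
      newrec$provenance <- rep(list("curated-addition"), nrow(newrec))
      out <- rbind(out, newrec)
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign one topology category to a protein record
#'
#' Categories are mutually exclusive with precedence GPI over multipass over
#' single-pass: a GPI-anchor flag wins regardless of transmembrane count;
#' otherwise two or more transmembrane segments give MULTIPASS, exactly one
#' gives SINGLE_PASS, none gives OTHER.
#'
#' @param tm_count Integer vector of transmembrane-segment counts (>= 0).
#' @param gpi_flag Logical vector, GPI-anchor annotation present.
#' @return Character vector of category labels (see [surfme_categories()]).
#' @export
categorize <- function(tm_count, gpi_flag) {
  tm_count <- as.integer(tm_count)
  stopifnot(all(tm_count >= 0L), length(tm_count) == length(gpi_flag))
  ifelse(gpi_flag, "GPI",
         ifelse(tm_count >= 2L, "MULTIPASS",
                ifelse(tm_count == 1L, "SINGLE_PASS", "OTHER")))
}

#' Build a surfaceome classifier from source catalogs and curation
#'
#' Composition of [merge_sources()] (duplicate removal), [apply_curation()]
#' (exclusion/addition curation) and [categorize()] (topology category
#' assignment). The result carries per-category summary counts.
#'
#' @param catalogs List of `source_catalog` objects.
#' @param curation A `curation_list` (default empty).
#' @param always_keep Accessions protected from exclusion, or a single source
#'   tag whose whole catalog is protected.
#' @param version_label Free-text version string recorded in the summary.
#' @return A `surfme_classifier`: list with `entries` (data.frame accession,
#'   symbol, category, provenance), `version_label`, and `summary` counts.
#' @export
build_classifier <- function(catalogs, curation = new_curation_list(),
                             always_keep = character(0),
                             version_label = "unversioned") {
  if (length(always_keep) == 1 && always_keep %in% source_tags()) {
    tag <- always_keep
    hit <- vapply(catalogs, function(ct) ct$source_tag == tag, logical(1))
    always_keep <- if (any(hit)) catalogs[[which(hit)[1]]]$records$accession
                   else character(0)
  }
  merged <- merge_sources(catalogs)
  curated <- apply_curation(merged, curation, always_keep)
  entries <- data.frame(
    accession = curated$accession,
    symbol = curated$symbol,
    category = categorize(curated$tm_count, curated$gpi_flag),
    stringsAsFactors = FALSE
  )
  entries$provenance <- curated$provenance
  entries <- entries[order(entries$accession), , drop = FALSE]
  rownames(entries) <- NULL
  new_classifier(entries, version_label)
}

#' Construct a classifier from an entries table
#'
#' @param entries data.frame with accession, symbol, category and a
#'   `provenance` list column; accessions must be unique.
#' @param version_label Free-text version string.
#' @return A `surfme_classifier` with summary counts per category.
#' @export
new_classifier <- function(entries, version_label = "unversioned") {
  stopifnot(!anyDuplicated(entries$accession))
  counts <- vapply(surfme_categories(),
                   function(k) sum(entries$category == k), integer(1))
  structure(list(entries = entries, version_label = version_label,
                 summary = c(as.list(counts), list(total = nrow(entries)))),
            class = "surfme_classifier")
}

#' @export
print.surfme_classifier <- function(x, ...) {
  s <- x$summary
  cat("<surfme_classifier>", s$total, "proteins (", x$version_label, ")\n")
  cat("  GPI:", s$GPI, " single-pass:", s$SINGLE_PASS,
      " multipass:", s$MULTIPASS, " other:", s$OTHER, "\n")
  invisible(x)
}

#' Write a classifier to disk
#'
#' Writes a TSV of entries (provenance semicolon-joined) and a JSON summary
#' next to it (`<path>.summary.json`). The pair round-trips losslessly via
#' [read_classifier()].
#'
#' @param classifier A `surfme_classifier`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(classifier, path) {
  e <- classifier$entries
  out <- data.frame(accession = e$accession, symbol = e$symbol,
                    category = e$category,
                    provenance = vapply(e$provenance, paste, character(1),
                                        collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- classifier$summary
  jsonlite::write_json(
    list(total = s$total, gpi = s$GPI, single_pass = s$SINGLE_PASS,
         multipass = s$MULTIPASS, other = s$OTHER,
         version_label = classifier$version_label),
    paste0(path, ".summary.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a classifier written by [write_classifier()]
#'
#' @param path Classifier TSV path.
#' @return A `surfme_classifier`.
#' @export
read_classifier <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("accession", "symbol", "category", "provenance")
  if (!all(need %in% names(df))) {
    stop("classifier file ", path, " must have columns ",
         paste(need, collapse = ","))
  }
  entries <- df[, c("accession", "symbol", "category")]
  entries$provenance <- strsplit(df$provenance, ";", fixed = TRUE)
  version <- "unversioned"
  sj <- paste0(path, ".summary.json")
  if (file.exists(sj)) version <- jsonlite::read_json(sj)$version_label
  new_classifier(entries, version)
}
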