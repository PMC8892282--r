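# Filtering of experimental identities to classifier members, with a
# category-composition report.

#' Filter identities or an abundance matrix to classifier members
#'
#' Retains the input identities (or matrix rows) whose accession, after
#' isoform stripping, is a classifier entry; original order is preserved.
#' When a classifier entry carries no accession in the input's namespace the
#' gene symbol is used as a fallback match and flagged in the report.
#'
#' @param x Character vector of accessions, or an `abundance_matrix`.
#' @param classifier A `surfme_classifier`.
#' @return List with `retained` (same type as `x`) and `report` (a
#'   `filter_report`: n_input, n_retained, n_dropped, category counts and
#'   fractions, n_symbol_matched).
#' @export
filter_to_classifier <- function(x, classifier) {
  stopifnot(inherits(classifier, "surfme_classifier"))
  if (nrow(classifier$entries) == 0) stop("classifier is empty")
  ids <- if (inherits(x, "abundance_matrix")) rownames(x$values) else x
  stripped <- strip_isoform(ids)
  hit <- stripped %in% classifier$entries$accession
  sym_hit <- !hit & stripped %in% classifier$entries$symbol
  keep <- hit | sym_hit
  if (!any(keep)) warning("no input identity matched the classifier")
  retained_ids <- ids[keep]
  matched_acc <- ifelse(
    hit[keep], stripped[keep],
    classifier$entries$accession[match(stripped[keep],
                                       classifier$entries$symbol)])
  report <- category_breakdown(matched_acc, classifier)
  report$n_input <- length(ids)
  report$n_retained <- sum(keep)
  report$n_dropped <- length(ids) - sum(keep)
  report$n_symbol_matched <- sum(sym_hit)
  class(report) <- "filter_report"
  retained <- if (inherits(x, "abundance_matrix")) {
    structure(list(values = x$values[keep, , drop = FALSE],
                   mask = x$mask[keep, , drop = FALSE], meta = x$meta),
              class = "abundance_matrix")
  } else retained_ids
  list(retained = retained, report = report)
}

#' Category composition of a retained identity set
#'
#' @param retained Character vector of accessions, each present in the
#'   classifier.
#' @param classifier A `surfme_classifier`.
#' @return List with `category_counts` and `category_fractions` (named by
#'   [surfme_categories()]).
#' @export
category_breakdown <- function(retained, classifier) {
  idx <- match(strip_isoform(retained), classifier$entries$accession)
  if (anyNA(idx)) {
    stop("identities not in the classifier: ",
         paste(utils::head(retained[is.na(idx)], 5), collapse = ", "))
  }
  cats <- classifier$entries$category[idx]
  counts <- vapply(surfme_categories(), function(k) sum(cats == k), integer(1))
  fracs <- if (length(cats)) counts / length(cats) else counts * NA_real_
  list(category_counts = as.list(counts), category_fractions = as.list(fracs))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$n_retained, "of", x$n_input,
      "identities retained (", x$n_dropped, "dropped )\n")
  cc <- unlist(x$category_counts)
  cat(" ", paste(names(cc), cc, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
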