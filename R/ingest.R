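# Abundance-table ingest and preprocessing: low-abundance resampling
# imputation of missing values, then total-intensity normalization.

#' Construct an abundance matrix with sample metadata
#'
#' @param values Numeric protein x sample matrix of linear-scale intensities,
#'   `NA` marking missing cells; rownames are accessions.
#' @param meta data.frame with one row per sample column:
#'   `sample_id,condition,fraction,subject,replicate`.
#' @return An `abundance_matrix`: list with `values`, `mask` (character
#'   matrix: "observed", "missing" or "imputed") and `meta`.
#' @export
new_abundance_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.data.frame(meta),
            ncol(values) == nrow(meta), !is.null(rownames(values)))
  need <- c("sample_id", "condition", "fraction", "subject", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ","))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  obs <- !is.na(values)
  if (any(values[obs] < 0)) stop("negative intensity values are not allowed")
  if (any(!is.finite(values[obs]))) stop("non-finite intensity values")
  colnames(values) <- meta$sample_id
  mask <- matrix(ifelse(is.na(values), "missing", "observed"),
                 nrow = nrow(values), dimnames = dimnames(values))
  structure(list(values = values, mask = mask, meta = meta),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix>", nrow(x$values), "proteins x",
      ncol(x$values), "samples;",
      sum(x$mask != "observed"), "missing/imputed cells\n")
  invisible(x)
}

#' Read a protein x sample abundance table with its metadata sheet
#'
#' Abundance TSV: first column `accession`, remaining columns one per sample,
#' blank/`NA` cells missing (zeros too when `zero_is_missing`). Metadata TSV:
#' `sample_id,condition,fraction,subject,replicate`. Duplicate protein rows
#' are aggregated by sum with a warning.
#'
#' @param path Abundance TSV path.
#' @param meta_path Metadata TSV path.
#' @param zero_is_missing Treat exported zeros as missing (exporter dialect).
#' @return An `abundance_matrix`.
#' @export
read_abundance_table <- function(path, meta_path, zero_is_missing = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"accession" %in% names(df)) {
    stop("abundance table ", path, " must have first column 'accession'")
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "accession"), drop = FALSE])
  storage.mode(vals) <- "double"
  unmatched <- c(setdiff(colnames(vals), meta$sample_id),
                 setdiff(meta$sample_id, colnames(vals)))
  if (length(unmatched)) {
    stop("metadata/sample-column mismatch: ", paste(unmatched, collapse = ", "))
  }
  vals <- vals[, meta$sample_id, drop = FALSE]
  rownames(vals) <- df$accession
  if (anyDuplicated(df$accession)) {
    warning("duplicate protein rows aggregated by sum: ",
            paste(unique(df$accession[duplicated(df$accession)]),
                  collapse = ", "))
    obs <- !is.na(vals)
    sums <- rowsum(ifelse(obs, vals, 0), df$accession)
    nobs <- rowsum(obs * 1L, df$accession)
    sums[nobs == 0] <- NA_real_  # all duplicates missing -> still missing
    vals <- sums
  }
  if (zero_is_missing) vals[vals == 0] <- NA_real_
  new_abundance_matrix(vals, meta)
}

#' Default preprocessing parameters
#'
#' @param impute_low_quantile Upper bound of the imputation window as a
#'   quantile of each sample's observed log2 intensities; default 0.05.
#' @param impute_floor_shift Log2 units subtracted from the sample's observed
#'   minimum to form the window's lower bound; default 1.
#' @param normalization_target `"median_total"` (scale every sample to the
#'   median column total) or `"fixed"`.
#' @param fixed_total Target column total when `normalization_target="fixed"`.
#' @param seed Integer seed for the imputation draws.
#' @return A named list of parameters.
#' @export
preprocess_params <- function(impute_low_quantile = 0.05,
                              impute_floor_shift = 1.0,
                              normalization_target = c("median_total", "fixed"),
                              fixed_total = NULL, seed = 1L) {
  stopifnot(impute_low_quantile > 0, impute_low_quantile <= 1)
  list(impute_low_quantile = impute_low_quantile,
       impute_floor_shift = impute_floor_shift,
       normalization_target = match.arg(normalization_target),
       fixed_total = fixed_total, seed = as.integer(seed))
}

#' Low-abundance resampling imputation
#'
#' Replaces each missing cell by `2^u`, `u` drawn uniformly from the sample's
#' low-abundance log2 window `[min_obs - impute_floor_shift, q]` where `q` is
#' the `impute_low_quantile` quantile of the sample's observed log2
#' intensities. Observed cells are never altered; the run is a pure function
#' of the input and the seed.
#'
#' @param am An `abundance_matrix`.
#' @param params See [preprocess_params()].
#' @return An `abundance_matrix` with no missing cells; imputed cells flagged
#'   `"imputed"` in the mask.
#' @export
impute_low_abundance <- function(am, params = preprocess_params()) {
  stopifnot(inherits(am, "abundance_matrix"))
  vals <- am$values
  mask <- am$mask
  all_missing <- colSums(mask == "observed") == 0
  if (any(all_missing)) {
    stop("sample(s) entirely missing: ",
         paste(colnames(vals)[all_missing], collapse = ", "))
  }
  few <- colSums(mask == "observed") < 2
  if (any(few)) {
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(vals)[few], collapse = ", "))
  }
  if (any(vals[mask == "observed"] <= 0)) {
    stop("imputation requires strictly positive observed intensities")
  }
  set.seed(params$seed)
  for (j in seq_len(ncol(vals))) {
    mis <- which(mask[, j] == "missing")
    if (!length(mis)) next
    obs_log2 <- log2(vals[mask[, j] == "observed", j])
    lo <- min(obs_log2) - params$impute_floor_shift
    hi <- stats::quantile(obs_log2, params$impute_low_quantile, names = FALSE)
    vals[mis, j] <- 2^stats::runif(length(mis), lo, hi)
    mask[mis, j] <- "imputed"
  }
  structure(list(values = vals, mask = mask, meta = am$meta),
            class = "abundance_matrix")
}

#' Total-intensity normalization
#'
#' Scales each sample column so all column totals equal the target (median of
#' the column totals by default). Missing cells must be imputed first, or
#' they are treated as zero with a warning.
#'
#' @param am An `abundance_matrix`.
#' @param params See [preprocess_params()].
#' @return A normalized `abundance_matrix`.
#' @export
normalize_total <- function(am, params = preprocess_params()) {
  stopifnot(inherits(am, "abundance_matrix"))
  vals <- am$values
  if (any(am$mask == "missing")) {
    warning("missing cells treated as zero during normalization; ",
            "impute first for the standard workflow")
    vals[am$mask == "missing"] <- 0
  }
  totals <- colSums(vals)
  zero <- totals == 0
  if (any(zero)) {
    stop("column total is zero for sample(s): ",
         paste(colnames(vals)[zero], collapse = ", "))
  }
  target <- switch(params$normalization_target,
                   median_total = stats::median(totals),
                   fixed = {
                     if (is.null(params$fixed_total))
                       stop("fixed normalization requires params$fixed_total")
                     params$fixed_total
                   })
  vals <- sweep(vals, 2, target / totals, `*`)
  structure(list(values = vals, mask = am$mask, meta = am$meta),
            class = "abundance_matrix")
}

#' Full preprocessing: imputation then normalization
#'
#' @inheritParams impute_low_abundance
#' @return A normalized `abundance_matrix` with no missing cells.
#' @export
preprocess <- function(am, params = preprocess_params()) {
  normalize_total(impute_low_abundance(am, params), params)
}

#' Write an abundance matrix (values + metadata) to TSV
#'
#' @param am An `abundance_matrix`.
#' @param path Abundance TSV path.
#' @param meta_path Metadata TSV path (default `<path>` with `.meta.tsv`).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(am, path,
                                  meta_path = paste0(path, ".meta.tsv")) {
  df <- data.frame(accession = rownames(am$values), am$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(am$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
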