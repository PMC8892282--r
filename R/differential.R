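# Differential protein expression: log2 fold changes, per-protein Welch
# tests with BH adjustment, the inclusive log2-FC up-regulation partition
# across fractions, and relative abundance against each protein's minimum
# sample.

# Resolve a sample selector against metadata. Selectors are either a logical
# / character vector of sample ids, or a one-sided formula-like string
# "column:VALUE" over the metadata columns.
resolve_samples <- function(am, selector) {
  meta <- am$meta
  if (is.logical(selector)) return(which(selector))
  if (is.numeric(selector)) return(as.integer(selector))
  if (length(selector) == 1 && grepl(":", selector, fixed = TRUE)) {
    parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
    col <- parts[1]; val <- parts[2]
    if (!col %in% names(meta)) stop("unknown metadata column: ", col)
    return(which(meta[[col]] == val))
  }
  idx <- match(selector, meta$sample_id)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(selector[is.na(idx)], collapse = ", "))
  idx
}

#' Per-protein log2 fold change between two sample groups
#'
#' `log2fc = mean(log2 a) - mean(log2 b)` per protein. Abundances must be
#' strictly positive (run [preprocess()] first).
#'
#' @param am An `abundance_matrix`.
#' @param group_a,group_b Sample selectors: sample ids, logical/numeric
#'   index, or `"column:VALUE"` over the metadata.
#' @return Named numeric vector of log2 fold changes (a vs b).
#' @export
log2_fold_change <- function(am, group_a, group_b) {
  ia <- resolve_samples(am, group_a)
  ib <- resolve_samples(am, group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be nonempty")
  vals <- am$values
  if (any(vals[, c(ia, ib)] <= 0, na.rm = TRUE) ||
      anyNA(vals[, c(ia, ib)])) {
    stop("abundances must be strictly positive and complete; ",
         "run preprocessing (imputation + normalization) first")
  }
  lv <- log2(vals)
  rowMeans(lv[, ia, drop = FALSE]) - rowMeans(lv[, ib, drop = FALSE])
}

#' Differential expression test (Welch t on log2 intensities)
#'
#' Two-sided Welch unequal-variance t-test per protein on log2 values, with
#' Benjamini-Hochberg adjustment across tested proteins. With fewer than two
#' replicates in either group, p and q are `NA` (fold change only). Proteins
#' with zero variance in both groups get p = 1 when group means are equal;
#' when means differ the p-value is set to the smallest representable double
#' and flagged.
#'
#' @inheritParams log2_fold_change
#' @return data.frame `dep_table`: accession, log2fc, mean_a, mean_b (log2),
#'   p_value, q_value, flag.
#' @export
dep_test <- function(am, group_a, group_b) {
  ia <- resolve_samples(am, group_a)
  ib <- resolve_samples(am, group_b)
  fc <- log2_fold_change(am, group_a, group_b)
  la <- log2(am$values[, ia, drop = FALSE])
  lb <- log2(am$values[, ib, drop = FALSE])
  n <- nrow(la)
  p <- rep(NA_real_, n)
  flag <- rep("", n)
  if (length(ia) >= 2 && length(ib) >= 2) {
    for (i in seq_len(n)) {
      a <- la[i, ]; b <- lb[i, ]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b)) {
          p[i] <- 1
        } else {
          p[i] <- .Machine$double.xmin
          flag[i] <- "zero-variance-separated"
        }
      } else {
        p[i] <- stats::t.test(a, b, var.equal = FALSE)$p.value
      }
    }
  } else {
    flag[] <- "insufficient-replicates"
  }
  out <- data.frame(
    accession = rownames(am$values),
    log2fc = unname(fc),
    mean_a = unname(rowMeans(la)),
    mean_b = unname(rowMeans(lb)),
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dep_table", "data.frame")
  out
}

#' Up-regulation partition across surface and endocytosed fractions
#'
#' Classifies proteins whose fold change reaches the inclusive cutoff in at
#' least one fraction into three disjoint sets: up-regulated at the surface
#' only, in both fractions, or in the endocytosed fraction only. A protein
#' absent from one fraction's fold-change map counts as not up-regulated
#' there.
#'
#' @param surface_fc,endo_fc Named numeric vectors of log2 fold changes.
#' @param cutoff Inclusive log2 fold-change cutoff; default 0.5.
#' @return List with character vectors `surface_only`, `both`,
#'   `endocytosed_only`, and the `cutoff`.
#' @export
upregulated_partition <- function(surface_fc, endo_fc, cutoff = 0.5) {
  universe <- union(names(surface_fc), names(endo_fc))
  s <- surface_fc[universe]; s[is.na(s)] <- -Inf
  e <- endo_fc[universe];    e[is.na(e)] <- -Inf
  up_s <- s >= cutoff
  up_e <- e >= cutoff
  list(surface_only = sort(universe[up_s & !up_e]),
       both = sort(universe[up_s & up_e]),
       endocytosed_only = sort(universe[up_e & !up_s]),
       cutoff = cutoff)
}

#' Relative abundance against each protein's minimum sample
#'
#' For every protein, expresses each sample's abundance as log2 fold over the
#' protein's lowest-abundance sample, so the minimum sample maps to 0 and all
#' values are nonnegative.
#'
#' @param am An `abundance_matrix` with strictly positive values.
#' @param proteins Optional character vector restricting the rows.
#' @return Numeric matrix of per-sample log2 fold over the minimum sample.
#' @export
relative_abundance_to_min <- function(am, proteins = NULL) {
  vals <- am$values
  if (!is.null(proteins)) {
    idx <- match(proteins, rownames(vals))
    if (anyNA(idx)) stop("proteins not in matrix: ",
                         paste(proteins[is.na(idx)], collapse = ", "))
    vals <- vals[idx, , drop = FALSE]
  }
  if (any(vals <= 0, na.rm = TRUE) || anyNA(vals)) {
    stop("relative abundance requires strictly positive, complete values")
  }
  log2(vals / apply(vals, 1, min))
}

#' Write a DEP table with partition labels
#'
#' @param dep A `dep_table` from [dep_test()].
#' @param partition Optional partition from [upregulated_partition()]; adds a
#'   `partition` column (surface_only/both/endocytosed_only/none).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dep_table <- function(dep, path, partition = NULL) {
  out <- as.data.frame(dep)
  if (!is.null(partition)) {
    lab <- rep("none", nrow(out))
    lab[out$accession %in% partition$surface_only] <- "surface_only"
    lab[out$accession %in% partition$both] <- "both"
    lab[out$accession %in% partition$endocytosed_only] <- "endocytosed_only"
    out$partition <- lab
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
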