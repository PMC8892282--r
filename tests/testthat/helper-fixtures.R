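# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A small classifier with known composition, built directly from entries.
tiny_classifier <- function(acc = c("P1", "P2", "P3", "P4"),
                            cats = c("GPI", "SINGLE_PASS", "MULTIPASS",
                                     "OTHER")) {
  entries <- data.frame(accession = acc, symbol = paste0("G", seq_along(acc)),
                        category = cats, stringsAsFactors = FALSE)
  entries$provenance <- rep(list("predictor"), nrow(entries))
  new_classifier(entries, "test")
}

# An abundance matrix from an explicit value matrix; one condition/fraction
# per sample unless metadata is supplied.
tiny_matrix <- function(values, conditions = NULL, fractions = NULL) {
  n <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  }
  meta <- data.frame(
    sample_id = if (is.null(colnames(values))) sprintf("s%d", seq_len(n))
                else colnames(values),
    condition = if (is.null(conditions)) rep("TWO_D", n) else conditions,
    fraction = if (is.null(fractions)) rep("SURFACE", n) else fractions,
    subject = "t", replicate = seq_len(n), stringsAsFactors = FALSE)
  new_abundance_matrix(values, meta)
}

# Write a source-catalog TSV and return its path.
write_source_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("source", tmpdir = dir, fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force weighted KS running-sum oracle: explicit position-by-position
# walk, independent of the vectorized implementation.
es_oracle <- function(ids, scores, geneset, w) {
  ord <- order(-scores, ids)
  ids <- ids[ord]; scores <- scores[ord]
  hits <- ids %in% geneset
  nr <- sum(abs(scores[hits])^w)
  n <- length(ids)
  rs <- numeric(n); cur <- 0; best <- 0
  for (i in seq_len(n)) {
    cur <- if (hits[i]) cur + abs(scores[i])^w / nr else cur - 1 / (n - sum(hits))
    rs[i] <- cur
    if (abs(cur) > abs(best)) best <- cur
  }
  list(es = best, running_sum = rs)
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size n
# from a universe of size N (N <= 12).
hyper_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% inset) >= k))
}
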