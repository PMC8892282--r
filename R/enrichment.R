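# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov running sum
# with gene-label permutation) and hypergeometric pathway
# overrepresentation with BH adjustment.

#' Build a ranked list from ids and scores
#'
#' Orders ids by descending score, ties broken by ascending id so the order
#' is deterministic.
#'
#' @param ids Character vector of unique protein ids.
#' @param scores Numeric ranking scores, same length.
#' @return A `ranked_list`: data.frame(id, score) in ranked order.
#' @export
ranked_list <- function(ids, scores) {
  stopifnot(length(ids) == length(scores), !anyDuplicated(ids),
            all(is.finite(scores)))
  ord <- order(-scores, ids)
  structure(data.frame(id = ids[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^w / N_R` at gene-set hits
#' (`N_R` = the sum of `|score|^w` over hits) and `-1/(N - N_hits)` at
#' misses; the enrichment score is the running-sum value of maximum absolute
#' deviation from zero. A gene set covering the entire list scores 1 by
#' convention.
#'
#' @param ranked A `ranked_list` (or data.frame with `id` and `score`).
#' @param geneset Character vector of gene-set ids.
#' @param weight_exponent Score weight `w >= 0`; 0 gives the classic
#'   unweighted KS statistic. Default 1.
#' @return List with `es` (in \[-1, 1\]) and `running_sum` (length N).
#' @export
enrichment_score <- function(ranked, geneset, weight_exponent = 1) {
  stopifnot(weight_exponent >= 0)
  ids <- ranked$id
  n <- length(ids)
  hit <- ids %in% geneset
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  if (nh == n) {
    return(list(es = 1, running_sum = cumsum(rep(1 / n, n))))
  }
  w <- abs(ranked$score)^weight_exponent
  nr <- sum(w[hit])
  if (nr == 0) stop("all hit scores are zero under this weight exponent")
  step <- ifelse(hit, w / nr, -1 / (n - nh))
  rs <- cumsum(step)
  es <- rs[which.max(abs(rs))]
  list(es = es, running_sum = rs)
}

#' Preranked gene-set enrichment with label-permutation p-value
#'
#' The null distribution is built by shuffling gene-set membership over the
#' list positions while keeping the scores fixed, so the test asks whether
#' the observed concentration of members near either end of the ranking
#' exceeds chance. The p-value is two-sided on `|es|` with the +1
#' pseudo-count: `p = (1 + #{|es_perm| >= |es_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of membership permutations (>= 100); default 1000.
#' @param seed Integer seed.
#' @return An `enrichment_result`: list with `es`, `p_perm`, `n_perm`,
#'   `weight_exponent`, `seed`, `running_sum`.
#' @export
preranked_gsea <- function(ranked, geneset, weight_exponent = 1,
                           n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  obs <- enrichment_score(ranked, geneset, weight_exponent)
  nh <- sum(ranked$id %in% geneset)
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_exponent
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    hit <- logical(n)
    hit[sample.int(n, nh)] <- TRUE
    nr <- sum(w[hit])
    if (nr == 0) { exceed <- exceed + 1L; next }  # degenerate null draw
    rs <- cumsum(ifelse(hit, w / nr, -1 / (n - nh)))
    if (max(abs(rs)) >= abs(obs$es)) exceed <- exceed + 1L
  }
  structure(list(es = obs$es, p_perm = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, weight_exponent = weight_exponent,
                 seed = seed, running_sum = obs$running_sum),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> es = %.4f, p_perm = %.4g (%d permutations)\n",
              x$es, x$p_perm, x$n_perm))
  invisible(x)
}

#' Hypergeometric pathway overrepresentation
#'
#' One-sided upper-tail hypergeometric test per pathway (probability of an
#' overlap at least as large as observed when drawing the query from the
#' universe without replacement), BH-adjusted across tested pathways and
#' sorted by p-value. Pathways are intersected with the universe before
#' testing.
#'
#' @param query Character vector of query ids (must lie in the universe).
#' @param pathways Named list of character vectors.
#' @param universe Character vector of background ids.
#' @return data.frame: pathway_id, overlap_k, pathway_size_K, query_size_n,
#'   universe_N, p_hyper, q_bh.
#' @export
overrepresentation <- function(query, pathways, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query ids outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(pathways), function(pid) {
    pw <- intersect(unique(pathways[[pid]]), universe)
    K <- length(pw)
    k <- length(intersect(query, pw))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, overlap_k = k, pathway_size_K = K,
               query_size_n = n, universe_N = N, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_bh <- stats::p.adjust(out$p_hyper, method = "BH")
  out[order(out$p_hyper, out$pathway_id), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Each line: name, description, then tab-separated member ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written on each line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
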