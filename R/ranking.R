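# Surface/endocytome overlap partition, abundance ranking of shared
# proteins, quadrant classification, and target prioritization.

#' Overlap partition of surface and endocytosed identity sets
#'
#' @param surface_ids,endo_ids Character vectors of identities.
#' @return List with `shared`, `surface_only`, `endocytosed_only` (sorted).
#' @export
overlap_partition <- function(surface_ids, endo_ids) {
  s <- unique(surface_ids); e <- unique(endo_ids)
  list(shared = sort(intersect(s, e)),
       surface_only = sort(setdiff(s, e)),
       endocytosed_only = sort(setdiff(e, s)))
}

#' Rank shared proteins by abundance in each fraction
#'
#' Dense unique integer ranks, 1 = lowest abundance, n = highest; ties are
#' broken by ascending accession so each axis is a strict permutation of
#' 1..n.
#'
#' @param shared Character vector of shared protein ids.
#' @param surface_abundance,endo_abundance Named positive numeric vectors
#'   covering all shared ids.
#' @return data.frame: accession, surface_rank, endo_rank.
#' @export
rank_abundances <- function(shared, surface_abundance, endo_abundance) {
  miss <- c(setdiff(shared, names(surface_abundance)),
            setdiff(shared, names(endo_abundance)))
  if (length(miss)) {
    stop("missing abundance for id(s): ",
         paste(unique(miss), collapse = ", "))
  }
  rank_one <- function(v) {
    ord <- order(v[shared], shared)  # ascending abundance, id tiebreak
    r <- integer(length(shared))
    r[ord] <- seq_along(shared)
    r
  }
  data.frame(accession = shared,
             surface_rank = rank_one(surface_abundance),
             endo_rank = rank_one(endo_abundance),
             stringsAsFactors = FALSE)
}

#' Classify ranked proteins into abundance quadrants
#'
#' An axis is HIGH when its rank exceeds `ceil(n/2)` (median split), LOW
#' otherwise; the quadrant combines the surface and endocytome axes. The
#' HIGH_HIGH quadrant — relatively high surface abundance and efficient
#' endocytic uptake — is the prioritized set for antibody-drug-conjugate or
#' radioimmunotherapy style targeting.
#'
#' @param ranks data.frame from [rank_abundances()].
#' @return The input with a `quadrant` column
#'   (HIGH_HIGH/HIGH_LOW/LOW_HIGH/LOW_LOW).
#' @export
quadrant_classify <- function(ranks) {
  n <- nrow(ranks)
  stopifnot(setequal(ranks$surface_rank, seq_len(n)),
            setequal(ranks$endo_rank, seq_len(n)))
  cut <- ceiling(n / 2)
  s_hi <- ranks$surface_rank > cut
  e_hi <- ranks$endo_rank > cut
  ranks$quadrant <- paste0(ifelse(s_hi, "HIGH", "LOW"), "_",
                           ifelse(e_hi, "HIGH", "LOW"))
  ranks
}

#' Prioritize HIGH_HIGH quadrant targets
#'
#' Orders HIGH_HIGH proteins by descending rank sum (surface + endocytome),
#' ties by ascending accession.
#'
#' @param ranked_targets data.frame from [quadrant_classify()].
#' @param top_k Optional truncation.
#' @return data.frame of prioritized candidates with a `priority_score`
#'   (rank sum) column.
#' @export
prioritize_targets <- function(ranked_targets, top_k = NULL) {
  hh <- ranked_targets[ranked_targets$quadrant == "HIGH_HIGH", , drop = FALSE]
  hh$priority_score <- hh$surface_rank + hh$endo_rank
  hh <- hh[order(-hh$priority_score, hh$accession), , drop = FALSE]
  rownames(hh) <- NULL
  if (!is.null(top_k)) hh <- utils::head(hh, top_k)
  hh
}
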