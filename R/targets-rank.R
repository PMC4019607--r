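# Aggregate site evidence per (miRNA, gene) pair, rank pairs by targeting
# strength, and apply the percentile retention filter plus optional duplex
# refinement.

#' Aggregate sites per pair and apply the percentile retention filter
#'
#' The aggregate score of a (miRNA, gene) pair is the sum of its sites'
#' context scores (more negative = stronger). 6mer sites are detected by the
#' scanner but excluded from the aggregate by default. Pairs are retained iff
#' their strength is at or beyond the \code{percentile}-th percentile of all
#' pairs' strengths, i.e. the strongest \code{(100 - percentile)\%} are kept
#' with ties at the cut retained (type-1 empirical quantile). With
#' \code{per_mirna = TRUE} the cut is taken within each miRNA instead of
#' globally. When \code{refine = TRUE} a pair is additionally required to have
#' best duplex score \code{>= duplex_threshold}; the two filters are
#' conjunctive.
#'
#' @param sites data.frame from \code{\link{scan_all_sites}} (columns
#'   \code{gene_id, mirna_id, start, end, site_type, context_score}).
#' @param duplexes optional data.frame with columns
#'   \code{mirna_id, gene_id, duplex_score} (best score per pair), required
#'   when \code{refine = TRUE}.
#' @param percentile retention percentile in (0, 100); default 95.
#' @param duplex_threshold minimum best duplex score for refinement.
#' @param refine apply the duplex filter to retention.
#' @param include_6mer include 6mer sites in the aggregate score.
#' @param per_mirna take the percentile cut within each miRNA.
#' @return data.frame with one row per pair: \code{mirna_id, gene_id, n_sites,
#'   best_site_type, aggregate_score, percentile_rank, refined, retained}.
#'   \code{percentile_rank} is the percentage of pairs with weaker-or-equal
#'   strength (100 = strongest). Rows are sorted by ascending aggregate score
#'   then ids.
#' @export
aggregate_and_rank <- function(sites, duplexes = NULL, percentile = 95,
                               duplex_threshold = 80, refine = FALSE,
                               include_6mer = FALSE, per_mirna = FALSE) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      n_sites = integer(0), best_site_type = character(0),
                      aggregate_score = numeric(0), percentile_rank = numeric(0),
                      refined = logical(0), retained = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(sites) || !nrow(sites)) return(empty)
  use <- if (include_6mer) sites else sites[sites$site_type != "6mer", , drop = FALSE]
  if (!nrow(use)) return(empty)
  key <- paste(use$mirna_id, use$gene_id, sep = "\r")
  agg <- data.frame(
    mirna_id = tapply(use$mirna_id, key, `[`, 1L),
    gene_id = tapply(use$gene_id, key, `[`, 1L),
    n_sites = as.integer(tapply(use$start, key, length)),
    best_site_type = tapply(use$site_type, key, function(tp) {
      SITE_TYPES[min(match(tp, SITE_TYPES))]
    }),
    aggregate_score = as.numeric(tapply(use$context_score, key, sum)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg$percentile_rank <- vapply(agg$aggregate_score, function(s) {
    100 * mean(agg$aggregate_score >= s)
  }, numeric(1))
  cut_group <- if (per_mirna) agg$mirna_id else rep("all", nrow(agg))
  agg$retained <- FALSE
  for (grp in unique(cut_group)) {
    idx <- cut_group == grp
    cutoff <- stats::quantile(agg$aggregate_score[idx],
                              probs = (100 - percentile) / 100,
                              type = 1, names = FALSE)
    agg$retained[idx] <- agg$aggregate_score[idx] <= cutoff
  }
  agg$refined <- NA
  if (!is.null(duplexes) && nrow(duplexes)) {
    dk <- paste(duplexes$mirna_id, duplexes$gene_id, sep = "\r")
    best <- tapply(duplexes$duplex_score, dk, max)
    ak <- paste(agg$mirna_id, agg$gene_id, sep = "\r")
    agg$refined <- as.numeric(best[ak]) >= duplex_threshold
    agg$refined[is.na(agg$refined)] <- FALSE
  }
  if (refine) {
    if (is.null(duplexes)) stop("refine = TRUE requires duplex scores")
    agg$retained <- agg$retained & agg$refined
  }
  agg <- agg[order(agg$aggregate_score, agg$mirna_id, agg$gene_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("mirna_id", "gene_id", "n_sites", "best_site_type",
          "aggregate_score", "percentile_rank", "refined", "retained")]
}

#' Full target prediction for sets of miRNAs and UTRs
#'
#' Scans every (miRNA, UTR) pair for seed sites, scores them, optionally runs
#' the duplex alignment for each pair's sites, and applies
#' \code{\link{aggregate_and_rank}}.
#'
#' @inheritParams scan_all_sites
#' @inheritParams aggregate_and_rank
#' @param extension duplex window extension (nt), see
#'   \code{\link{duplex_align}}.
#' @return list with elements \code{sites} (all scored sites) and
#'   \code{predictions} (the ranked pair table).
#' @export
predict_targets <- function(mirnas, utrs, percentile = 95, refine = TRUE,
                            duplex_threshold = 80, include_6mer = FALSE,
                            per_mirna = FALSE, extension = 25) {
  mirnas <- as_rna(mirnas); utrs <- as_rna(utrs)
  sites <- scan_all_sites(mirnas, utrs)
  duplexes <- NULL
  if (nrow(sites)) {
    scores <- vapply(seq_len(nrow(sites)), function(i) {
      duplex_align(mirnas[[sites$mirna_id[i]]], utrs[[sites$gene_id[i]]],
                   sites$start[i], sites$end[i], extension = extension)$score
    }, numeric(1))
    duplexes <- data.frame(mirna_id = sites$mirna_id, gene_id = sites$gene_id,
                           duplex_score = scores, stringsAsFactors = FALSE)
  }
  preds <- aggregate_and_rank(sites, duplexes, percentile = percentile,
                              duplex_threshold = duplex_threshold,
                              refine = refine, include_6mer = include_6mer,
                              per_mirna = per_mirna)
  list(sites = sites, predictions = preds)
}
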