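# Linkage stage: Pearson correlation of miRNA and candidate-target
# trajectories over the shared timepoint grid, edge gating on sign and
# significance, and bipartite network export.

#' Pearson correlation test between two trajectories
#'
#' Standard product-moment correlation with a two-sided p-value from
#' \code{t = r sqrt((n-2)/(1-r^2))} on \code{n - 2} degrees of freedom
#' (via \code{stats::cor.test}); \code{|r| = 1} is reported with \code{p = 0}.
#' Both series must be non-constant and share the same grid.
#'
#' @param x,y numeric vectors on the same timepoint grid, length >= 3.
#' @param x_id,y_id identifiers used in error messages.
#' @param alternative sidedness of the test (default two-sided).
#' @return list \code{r}, \code{p}, \code{n}.
#' @export
pearson_r_test <- function(x, y, x_id = "x", y_id = "y",
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) {
    stop("trajectory grids differ in length for ", x_id, " vs ", y_id)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 shared timepoints")
  if (stats::sd(x) == 0) stop("constant trajectory for ", x_id,
                              ": correlation undefined")
  if (stats::sd(y) == 0) stop("constant trajectory for ", y_id,
                              ": correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  r <- unname(ct$estimate); p <- unname(ct$p.value)
  if (1 - abs(r) < 1e-12) {   # numerically perfect correlation: p = 0 convention
    r <- sign(r); p <- 0
  }
  list(r = r, p = p, n = n)
}

# Align two named trajectory vectors on their shared timepoints (grid order
# taken from x).
shared_grid <- function(x, y) {
  tps <- intersect(names(x), names(y))
  list(x = x[tps], y = y[tps], timepoints = tps)
}

#' Gate predicted miRNA-target pairs on temporal anti-correlation
#'
#' For every (miRNA, gene) pair with a retained target prediction and
#' trajectories on the shared grid, computes the Pearson correlation of the
#' log2 trajectories (raw scale with \code{log2_scale = FALSE}) and emits a
#' network edge when the gate passes: in mode \code{"negative"} iff
#' \code{r < 0} and \code{p < alpha}; in mode \code{"any"} iff
#' \code{p < alpha}. \code{direction_consistent} is TRUE when the miRNA's
#' differential direction opposes the gene's net trajectory direction
#' (down-regulated miRNA with rising target or vice versa), falling back to
#' \code{r < 0} when no call is available for the miRNA.
#'
#' @param mirna_trajs named list (or row-named matrix) of miRNA trajectories:
#'   per miRNA a named numeric vector of positive values per timepoint
#'   (e.g. per-timepoint fold changes).
#' @param gene_trajs same structure for candidate target genes.
#' @param predictions prediction table from \code{\link{aggregate_and_rank}};
#'   only rows with \code{retained == TRUE} are considered.
#' @param alpha significance level (default 0.05).
#' @param mode \code{"negative"} (default) or \code{"any"}.
#' @param calls optional differential-call table from
#'   \code{\link{select_differential}} (used for direction consistency).
#' @param log2_scale correlate log2-transformed values (default TRUE).
#' @param alternative sidedness passed to \code{\link{pearson_r_test}}.
#' @return data.frame of edges sorted by ascending p (ties by ids):
#'   \code{mirna_id, gene_id, r, p, n, direction_consistent, n_sites,
#'   best_site_type}. Pairs lacking a trajectory are skipped; their number is
#'   reported via a message.
#' @export
predict_links <- function(mirna_trajs, gene_trajs, predictions, alpha = 0.05,
                          mode = c("negative", "any"), calls = NULL,
                          log2_scale = TRUE,
                          alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (is.matrix(mirna_trajs)) {
    mirna_trajs <- stats::setNames(split(mirna_trajs, row(mirna_trajs)),
                                   rownames(mirna_trajs))
  }
  preds <- predictions[predictions$retained, , drop = FALSE]
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      direction_consistent = logical(0), n_sites = integer(0),
                      best_site_type = character(0), stringsAsFactors = FALSE)
  if (!nrow(preds)) return(empty)
  dir_of <- NULL
  if (!is.null(calls) && nrow(calls)) {
    dir_of <- stats::setNames(calls$direction, calls$entity)
  }
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(preds))) {
    m <- preds$mirna_id[i]; g <- preds$gene_id[i]
    if (is.null(mirna_trajs[[m]]) || is.null(gene_trajs[[g]])) {
      skipped <- skipped + 1L; next
    }
    al <- shared_grid(mirna_trajs[[m]], gene_trajs[[g]])
    x <- al$x; y <- al$y
    if (log2_scale) { x <- log2(x); y <- log2(y) }
    tst <- pearson_r_test(x, y, x_id = m, y_id = g, alternative = alternative)
    pass <- tst$p < alpha && (mode == "any" || tst$r < 0)
    if (!pass) next
    gene_ratio <- al$y[length(al$y)] / al$y[1]
    dc <- if (!is.null(dir_of) && !is.na(dir_of[m])) {
      (dir_of[m] == "down" && gene_ratio > 1) ||
        (dir_of[m] == "up" && gene_ratio < 1) || tst$r < 0
    } else tst$r < 0
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = m, gene_id = g, r = tst$r, p = tst$p, n = tst$n,
      direction_consistent = unname(dc), n_sites = preds$n_sites[i],
      best_site_type = preds$best_site_type[i], stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " predicted pair(s) lacked a trajectory and were skipped")
  if (!length(rows)) return(empty)
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$p, edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export the bipartite miRNA-target network
#'
#' Writes a deterministic edge-list TSV and a GraphML file with a
#' \code{node_type} attribute (\code{"mirna"} / \code{"gene"}).
#'
#' @param edges edge table from \code{\link{predict_links}}.
#' @param tsv_path,graphml_path output file paths (either may be NULL to skip).
#' @return invisible list of written paths.
#' @export
export_network <- function(edges, tsv_path = NULL, graphml_path = NULL) {
  cols <- c("mirna_id", "gene_id", "r", "p", "n_sites", "best_site_type",
            "direction_consistent")
  tab <- if (nrow(edges)) edges[, cols, drop = FALSE] else
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  if (!is.null(tsv_path)) write_tsv_plain(tab, tsv_path)
  if (!is.null(graphml_path)) {
    nodes <- data.frame(
      name = c(unique(tab$mirna_id), unique(tab$gene_id)),
      node_type = c(rep("mirna", length(unique(tab$mirna_id))),
                    rep("gene", length(unique(tab$gene_id)))),
      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(tab, directed = TRUE, vertices = nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(tsv = tsv_path, graphml = graphml_path))
}
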