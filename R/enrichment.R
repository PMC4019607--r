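# Pathway enrichment: right-tailed Fisher exact test (hypergeometric upper
# tail, summed in log space) on the overlap between the filtered target set
# and each pathway, ranked with deterministic tie-breaking.

#' Read a GMT pathway file
#'
#' Each line: pathway name, description, then tab-separated member gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors (names = pathway ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  do.call(c, out)
}

#' Write a GMT pathway file
#'
#' @param pathways named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-pathway descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Right-tailed Fisher exact test on an overlap
#'
#' Probability that a hypergeometric draw of \code{n} genes from a universe of
#' \code{N} containing a pathway of size \code{K} overlaps it in at least
#' \code{k} genes:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}}
#' Terms are accumulated in log space (log-sum-exp) for numerical stability.
#'
#' @param k observed overlap; \code{0 <= k <= min(n, K)}.
#' @param n query (draw) size; \code{n <= N}.
#' @param K pathway size; \code{K <= N}.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @examples
#' fisher_right_tail(4, 4, 5, 10)  # 5/210
#' @export
fisher_right_tail <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || n > N || K > N || k > min(n, K)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  if (k == 0) return(1.0)
  i <- k:min(n, K)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lg)
  exp(m + log(sum(exp(lg - m))))
}

#' Rank pathways by enrichment of a query gene set
#'
#' One right-tailed Fisher test per pathway; results are ranked by ascending
#' p, ties broken by descending ratio (\code{k/K}) then lexical pathway id,
#' and the top \code{top_k} returned. The universe defaults to the union of
#' all pathway genes; query genes outside the universe are clipped with a
#' message. Optional Benjamini-Hochberg q-values (computed across all
#' pathways before truncation) are attached without changing the rank order.
#'
#' @param query character vector of gene ids.
#' @param pathways named list of pathway gene sets (e.g. \code{\link{read_gmt}}).
#' @param universe optional universe gene ids; default
#'   \code{unique(unlist(pathways))}.
#' @param top_k number of top pathways to return (default 30).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame \code{pathway, k, K, n, N, p, ratio, rank} (+ \code{q}
#'   when \code{adjust = "BH"}).
#' @export
enrich_pathways <- function(query, pathways, universe = NULL, top_k = 30,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(pathways)) {
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      ratio = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(universe)) universe <- unique(unlist(pathways, use.names = FALSE))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe were clipped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  res <- data.frame(
    pathway = names(pathways),
    k = vapply(pathways, function(g) length(intersect(g, query)), integer(1)),
    K = vapply(pathways, function(g) length(intersect(g, universe)), integer(1)),
    n = n, N = N, stringsAsFactors = FALSE)
  res$p <- mapply(fisher_right_tail, res$k, MoreArgs = list(n = n, N = N),
                  K = res$K)
  res$ratio <- res$k / res$K
  if (adjust == "BH") res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, -res$ratio, res$pathway), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- utils::head(res, top_k)
  rownames(res) <- NULL
  res
}

#' Coverage of the query by the top enriched pathways
#'
#' Reports how many query genes fall in the union of the returned top
#' pathways, and that count as a percentage of the query (rounded to one
#' decimal, the convention used for pathway-coverage summaries).
#'
#' @param query character vector of gene ids (as passed to
#'   \code{\link{enrich_pathways}}).
#' @param results enrichment table from \code{\link{enrich_pathways}}.
#' @param pathways the pathway collection used.
#' @return list \code{covered_n}, \code{query_n}, \code{covered_fraction}
#'   (proportion), \code{covered_pct} (percentage, 1 decimal).
#' @export
enrichment_summary <- function(query, results, pathways) {
  query <- unique(as.character(query))
  top_union <- unique(unlist(pathways[results$pathway], use.names = FALSE))
  covered <- length(intersect(query, top_union))
  list(covered_n = covered, query_n = length(query),
       covered_fraction = covered / length(query),
       covered_pct = round(100 * covered / length(query), 1))
}
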