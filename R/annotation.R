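# Annotation-term filter: restrict a gene set to genes carrying an exact
# query term (case-insensitive full-string equality) with minimum evidence.

#' Default eosinophil-biology query terms
#'
#' The standard term list used to restrict predicted targets to genes with an
#' exact annotation link to eosinophil biology.
#'
#' @return character vector of terms (lower case).
#' @export
default_query_terms <- function() {
  c("eosinophils", "eosinophilia", "il-3", "il-5", "eosinophil peroxidase",
    "eosinophil cationic protein", "eosinophil granule proteins",
    "eosinophil major basic protein", "eosinophil-derived neurotoxin")
}

#' Read a gene-term annotation map
#'
#' @param path TSV with columns \code{gene}, \code{term},
#'   \code{evidence_count} (number of supporting literature references,
#'   integer >= 0). Terms are case-folded on read.
#' @return data.frame \code{gene}, \code{term}, \code{evidence_count}.
#' @export
read_annotation_map <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("gene", "term", "evidence_count") %in% names(df)))
  df$term <- tolower(df$term)
  df$evidence_count <- as.integer(df$evidence_count)
  if (any(df$evidence_count < 0)) stop("negative evidence_count")
  df
}

#' Filter genes by exact annotation-term matching
#'
#' A gene is retained iff at least one of its annotations has a term exactly
#' equal (after case folding) to a query term, with
#' \code{evidence_count >= min_evidence}. Substring matches never count.
#' Genes absent from the annotation map are excluded; their number is
#' reported via a message.
#'
#' @param genes character vector of gene ids to filter.
#' @param annotation annotation map data.frame
#'   (\code{gene, term, evidence_count}).
#' @param terms query terms (case-insensitive exact match); empty set gives
#'   an empty result.
#' @param min_evidence minimum evidence count (default 1).
#' @return sorted character vector of retained gene ids.
#' @export
filter_by_terms <- function(genes, annotation, terms = default_query_terms(),
                            min_evidence = 1L) {
  genes <- unique(as.character(genes))
  if (!length(terms)) return(character(0))
  unknown <- setdiff(genes, annotation$gene)
  if (length(unknown)) {
    message(length(unknown), " gene(s) absent from the annotation map")
  }
  hit <- annotation$gene %in% genes &
    tolower(annotation$term) %in% tolower(terms) &
    annotation$evidence_count >= min_evidence
  sort(unique(annotation$gene[hit]))
}

#' Intersect predicted and annotated gene sets
#'
#' @param predicted,annotated character vectors of gene ids.
#' @return sorted intersection.
#' @export
intersect_targets <- function(predicted, annotated) {
  sort(intersect(unique(predicted), unique(annotated)))
}
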