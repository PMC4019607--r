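# Canonical seed-site scanning. Site types follow the standard definitions:
# the seed is miRNA positions 2-8 (1-based from the 5' end); a site is the
# Watson-Crick match to the seed on the UTR sense strand, optionally extended
# by a match to position 8 and/or an adenosine opposite position 1.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
SITE_WIDTHS <- c(`8mer` = 8L, `7mer-m8` = 7L, `7mer-A1` = 7L, `6mer` = 6L)

#' UTR match strings for the canonical site types of a miRNA
#'
#' With \code{rc()} the reverse complement: \code{7mer-m8 = rc(pos 2-8)},
#' \code{8mer = rc(pos 2-8) + "A"}, \code{7mer-A1 = rc(pos 2-7) + "A"},
#' \code{6mer = rc(pos 2-7)}. The terminal \code{"A"} is an adenosine required
#' in the UTR regardless of the identity of miRNA position 1.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3', DNA or RNA alphabet,
#'   length >= 8.
#' @return named character vector with elements \code{8mer}, \code{7mer-m8},
#'   \code{7mer-A1}, \code{6mer} (RNA alphabet, UTR sense strand).
#' @examples
#' site_patterns("UGGAAUGUAAAGAAGUAUGUAU")  # miR-1; 8mer is "ACAUUCCA"
#' @export
site_patterns <- function(mirna_seq) {
  s <- as_rna(mirna_seq)
  if (nchar(s) < 8L) stop("miRNA must be at least 8 nt to define seed sites")
  seed28 <- substr(s, 2L, 8L)
  seed27 <- substr(s, 2L, 7L)
  c(`8mer`    = paste0(revcomp_rna(seed28), "A"),
    `7mer-m8` = revcomp_rna(seed28),
    `7mer-A1` = paste0(revcomp_rna(seed27), "A"),
    `6mer`    = revcomp_rna(seed27))
}

# All start offsets (0-based) of fixed pattern in subject; N never matches.
fixed_match_starts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Scan a 3'UTR for canonical seed sites of one miRNA
#'
#' Reports every occurrence of every site pattern, resolving overlapping
#' windows by type precedence \code{8mer > 7mer-m8 > 7mer-A1 > 6mer}: windows
#' are accepted greedily in precedence order (then by start), and a window
#' overlapping an already accepted one is dropped, so e.g. the 7mer contained
#' in a reported 8mer window is not reported separately. Coordinates are
#' 0-based half-open on the UTR sense strand. Output rows are ordered by
#' start, then type precedence.
#'
#' @param mirna_seq mature miRNA sequence (5'->3').
#' @param utr_seq 3'UTR sequence (5'->3'), DNA or RNA alphabet; \code{N}
#'   matches nothing.
#' @param mirna_id,gene_id identifiers copied into the output.
#' @return data.frame with columns \code{gene_id}, \code{mirna_id},
#'   \code{start}, \code{end}, \code{site_type}.
#' @export
scan_sites <- function(mirna_seq, utr_seq, mirna_id = "miRNA", gene_id = "gene") {
  utr <- as_rna(utr_seq)
  pats <- site_patterns(mirna_seq)
  cand <- do.call(rbind, lapply(SITE_TYPES, function(tp) {
    st <- fixed_match_starts(pats[[tp]], utr)
    if (!length(st)) return(NULL)
    data.frame(start = st, end = st + SITE_WIDTHS[[tp]], site_type = tp,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(gene_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (is.null(cand) || !nrow(cand)) return(empty)
  prec <- match(cand$site_type, SITE_TYPES)
  cand <- cand[order(prec, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < occ_end & cand$end[i] > occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start, match(out$site_type, SITE_TYPES)), , drop = FALSE]
  data.frame(gene_id = gene_id, mirna_id = mirna_id, out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Context-style score for a seed site
#'
#' A surrogate repression-strength score (more negative = stronger) combining
#' the site-type base contribution with two local-sequence adjustments:
#' \deqn{score = base(type) + w_{AU} (0.5 - f_{AU}) + w_{pos} \min(d, cap)/cap}
#' where \eqn{f_{AU}} is the AU fraction of the pooled up-to-30-nt flanks on
#' each side of the site (0.5 if both flanks are empty) and \eqn{d} is the
#' distance from the site midpoint to the nearer UTR end. The coefficients are
#' surrogate values chosen to preserve the canonical site-type ordering; they
#' are not fitted to repression data and are fully configurable.
#'
#' @param site_type one of \code{"8mer"}, \code{"7mer-m8"}, \code{"7mer-A1"},
#'   \code{"6mer"}.
#' @param start,end 0-based half-open site coordinates on the UTR.
#' @param utr_seq the UTR sequence.
#' @param base named numeric vector of per-type base scores.
#' @param w_au,w_pos,cap adjustment weights and the positional saturation
#'   distance in nucleotides.
#' @param flank maximum flank width considered on each side (nt).
#' @return numeric score.
#' @export
context_score <- function(site_type, start, end, utr_seq,
                          base = c(`8mer` = -0.31, `7mer-m8` = -0.16,
                                   `7mer-A1` = -0.10, `6mer` = -0.02),
                          w_au = 0.20, w_pos = 0.10, cap = 1500, flank = 30) {
  utr <- as_rna(utr_seq)
  len <- nchar(utr)
  stopifnot(start >= 0, end <= len, end > start)
  left <- substr(utr, max(1L, start - flank + 1L), start)   # 1-based slice
  right <- substr(utr, end + 1L, min(len, end + flank))
  fl <- paste0(left, right)
  au_frac <- if (nchar(fl) == 0L) 0.5 else {
    ch <- strsplit(fl, "", fixed = TRUE)[[1]]
    mean(ch %in% c("A", "U"))
  }
  mid <- (start + end) / 2
  d_end <- min(mid, len - mid)
  unname(base[[site_type]] + w_au * (0.5 - au_frac) + w_pos * min(d_end, cap) / cap)
}

#' Scan and score all sites for sets of miRNAs and UTRs
#'
#' Convenience wrapper running \code{\link{scan_sites}} over every
#' (miRNA, UTR) pair and attaching \code{\link{context_score}} to each site.
#'
#' @param mirnas named character vector of mature miRNA sequences
#'   (names = miRNA ids).
#' @param utrs named character vector of 3'UTR sequences (names = gene ids).
#' @param ... passed to \code{\link{context_score}}.
#' @return data.frame of sites with a \code{context_score} column.
#' @export
scan_all_sites <- function(mirnas, utrs, ...) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(utrs)))
  res <- list()
  for (m in names(mirnas)) {
    for (g in names(utrs)) {
      s <- scan_sites(mirnas[[m]], utrs[[g]], mirna_id = m, gene_id = g)
      if (nrow(s)) res[[length(res) + 1L]] <- s
    }
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), context_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, res)
  sites$context_score <- vapply(seq_len(nrow(sites)), function(i) {
    context_score(sites$site_type[i], sites$start[i], sites$end[i],
                  utrs[[sites$gene_id[i]]], ...)
  }, numeric(1))
  rownames(sites) <- NULL
  sites
}
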