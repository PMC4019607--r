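# Duplex refinement: a single local-alignment pass of the reversed miRNA
# (3'->5') against the UTR window around a seed site, with miRanda-style
# column scoring and doubled weight for columns pairing the seed (miRNA
# positions 2-8).

PAIR_WC <- 5; PAIR_GU <- 2; PAIR_MM <- -3
GAP_OPEN <- -8; GAP_EXT <- -2

# Score of pairing miRNA base a (RNA) with UTR base b, antiparallel duplex.
pair_score <- function(a, b) {
  if (a == "N" || b == "N") return(PAIR_MM)
  wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")
  if (wc) return(PAIR_WC)
  gu <- (a == "G" && b == "U") || (a == "U" && b == "G")
  if (gu) return(PAIR_GU) else PAIR_MM
}

# Core local-alignment DP (Gotoh, affine gaps). mir_rev is the reversed miRNA;
# seed columns (original miRNA positions 2-8) have their pair/mismatch scores
# doubled; gap penalties are never doubled. Returns the best local score
# (>= 0; 0 means the empty alignment).
duplex_dp <- function(mir_rev, win) {
  m <- nchar(mir_rev); n <- nchar(win)
  if (m == 0L || n == 0L) return(0)
  a <- strsplit(mir_rev, "", fixed = TRUE)[[1]]
  b <- strsplit(win, "", fixed = TRUE)[[1]]
  # original miRNA position of reversed index i is m - i + 1
  seed_mult <- ifelse((m - seq_len(m) + 1L) >= 2L & (m - seq_len(m) + 1L) <= 8L, 2, 1)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)  # best ending in a pair column
  X <- matrix(NEG, m + 1L, n + 1L)  # best ending in a gap consuming miRNA
  Y <- matrix(NEG, m + 1L, n + 1L)  # best ending in a gap consuming UTR
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- pair_score(a[i], b[j]) * seed_mult[i]
      prev <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1L, j + 1L] <- prev + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + GAP_OPEN,
                               X[i, j + 1L] + GAP_EXT,
                               Y[i, j + 1L] + GAP_OPEN)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + GAP_OPEN,
                               Y[i + 1L, j] + GAP_EXT,
                               X[i + 1L, j] + GAP_OPEN)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

#' Duplex alignment of a miRNA against the UTR window around a site
#'
#' Local alignment (dynamic programming, affine gaps) of the reversed miRNA
#' against the UTR window \code{[start - extension, end + extension)}, clipped
#' at the UTR bounds. Column scoring: Watson-Crick pair +5, G:U wobble +2,
#' mismatch -3, gap open -8, gap extend -2; pair/mismatch scores are doubled
#' when the column pairs a seed base (miRNA positions 2-8). Gap penalties are
#' never doubled. The best local score is returned (0 for the empty
#' alignment).
#'
#' @param mirna_seq mature miRNA sequence (5'->3').
#' @param utr_seq 3'UTR sequence.
#' @param start,end 0-based half-open site coordinates (from
#'   \code{\link{scan_sites}}).
#' @param extension window extension on each side of the site, nt.
#' @return list with \code{score}, \code{window_start}, \code{window_end}
#'   (0-based half-open window actually aligned).
#' @examples
#' # a fully complementary 22-nt window scores 7*5*2 + 15*5 = 145
#' m <- "UGGAAUGUAAAGAAGUAUGUAU"
#' w <- revcomp_rna(m)
#' duplex_align(m, w, 0, nchar(w), extension = 0)$score
#' @export
duplex_align <- function(mirna_seq, utr_seq, start, end, extension = 25) {
  mir <- as_rna(mirna_seq)
  utr <- as_rna(utr_seq)
  len <- nchar(utr)
  ws <- max(0L, as.integer(start) - as.integer(extension))
  we <- min(len, as.integer(end) + as.integer(extension))
  win <- substr(utr, ws + 1L, we)
  mir_rev <- paste(rev(strsplit(mir, "", fixed = TRUE)[[1]]), collapse = "")
  list(score = duplex_dp(mir_rev, win), window_start = ws, window_end = we)
}
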