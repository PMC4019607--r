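# Independent oracles used across the suite. Each one recomputes a quantity
# by a route that shares no code with the implementation it checks.

# Naive seed-site oracle: checks every window of the UTR for string equality
# with each site pattern (patterns recomputed here from first principles),
# then applies the same precedence rules via a position-occupancy vector.
naive_scan_oracle <- function(mirna_seq, utr_seq) {
  rc1 <- function(s) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
  }
  s <- chartr("Tt", "Uu", toupper(mirna_seq))
  utr <- chartr("Tt", "Uu", toupper(utr_seq))
  pats <- list(
    `8mer` = paste0(rc1(substr(s, 2, 8)), "A"),
    `7mer-m8` = rc1(substr(s, 2, 8)),
    `7mer-A1` = paste0(rc1(substr(s, 2, 7)), "A"),
    `6mer` = rc1(substr(s, 2, 7)))
  L <- nchar(utr)
  occupied <- rep(FALSE, L)
  rows <- list()
  for (tp in names(pats)) {
    w <- nchar(pats[[tp]])
    if (L < w) next
    windows <- substring(utr, 1:(L - w + 1), w:L)
    for (st in which(windows == pats[[tp]])) {
      span <- st:(st + w - 1)           # 1-based positions
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        start = st - 1L, end = st + w - 1L, site_type = tp,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  prec <- c(`8mer` = 1, `7mer-m8` = 2, `7mer-A1` = 3, `6mer` = 4)
  out <- out[order(out$start, prec[out$site_type]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force hypergeometric right tail by enumerating every n-subset of a
# universe of N genes of which the first K form the pathway.
brute_force_fisher <- function(k, n, K, N) {
  if (k == 0) return(1.0)
  if (n == 0) return(if (k == 0) 1.0 else 0.0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Exhaustive local-duplex enumeration (memoized recursion over all alignment
# paths with affine gaps). a = reversed miRNA, b = UTR window.
brute_force_duplex <- function(a_str, b_str) {
  a <- strsplit(a_str, "", fixed = TRUE)[[1]]
  b <- strsplit(b_str, "", fixed = TRUE)[[1]]
  m <- length(a); n <- length(b)
  pair <- function(x, y) {
    if (x == "N" || y == "N") return(-3)
    wc <- paste0(x, y) %in% c("AU", "UA", "GC", "CG")
    if (wc) return(5)
    if (paste0(x, y) %in% c("GU", "UG")) return(2)
    -3
  }
  mult <- function(i) if ((m - i + 1) >= 2 && (m - i + 1) <= 8) 2 else 1
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0
    if (i <= m && j <= n) {
      best <- max(best, pair(a[i], b[j]) * mult(i) + rec(i + 1, j + 1, "M"))
    }
    if (i <= m) {
      best <- max(best, (if (last == "X") -2 else -8) + rec(i + 1, j, "X"))
    }
    if (j <= n) {
      best <- max(best, (if (last == "Y") -2 else -8) + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- max(best, pair(a[i], b[j]) * mult(i) + rec(i + 1, j + 1, "M"))
    }
  }
  best
}

# Covariance-formula Pearson r and two-sided p, written independently of
# stats::cor.test.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

# Random RNA string helper for fixtures.
rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# A small, fast simulation configuration used by several tests.
small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    rng_seed = seed,
    n_mirna = 10L, n_genes = 14L, utr_length = 300L,
    planted_up = stats::setNames(c(8, 20), c("mir-01", "mir-02")),
    planted_down = stats::setNames(c(1 / 8, 1 / 50), c("mir-03", "mir-04")),
    planted_sites = data.frame(
      mirna_id = c("mir-01", "mir-02", "mir-03", "mir-04"),
      gene_id = c("gene-01", "gene-02", "gene-03", "gene-04"),
      site_type = c("8mer", "7mer-m8", "8mer", "7mer-A1"),
      stringsAsFactors = FALSE),
    planted_links = data.frame(
      mirna_id = c("mir-01", "mir-02", "mir-03", "mir-04"),
      gene_id = c("gene-01", "gene-02", "gene-03", "gene-04"),
      sign = -1, strength = 0.95, stringsAsFactors = FALSE),
    n_pathways = 8L, enriched_pathway_overlap = 3L,
    pathway_size_range = c(5L, 10L))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(simulation_config, defaults)
}
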