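test_that("site patterns are the reverse complements of the seed", {
  p <- site_patterns("UGGAAUGUAAAGAAGUAUGUAU")
  expect_equal(unname(p["8mer"]), "ACAUUCCA")
  expect_equal(unname(p["7mer-m8"]), "ACAUUCC")
  expect_equal(unname(p["7mer-A1"]), "CAUUCCA")
  expect_equal(unname(p["6mer"]), "CAUUCC")

  # complement symmetry and the definitional 8mer = 7mer-m8 + "A"
  expect_equal(unname(site_patterns(strrep("A", 22))["7mer-m8"]), "UUUUUUU")
  for (i in 1:20) {
    p <- site_patterns(rand_rna(22))
    expect_equal(unname(p["8mer"]), paste0(p["7mer-m8"], "A"))
    expect_equal(unname(p["7mer-A1"]), paste0(p["6mer"], "A"))
  }
  expect_error(site_patterns("ACGUACG"), "at least 8")
})

test_that("scanner classifies canonical windows with type precedence", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  s8 <- scan_sites(m, "GGGGACAUUCCAGGGG")
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$site_type, "8mer")
  expect_equal(c(s8$start, s8$end), c(4L, 12L))

  s7 <- scan_sites(m, "GGGGACAUUCCGGGGG")
  expect_equal(s7$site_type, "7mer-m8")
  expect_equal(c(s7$start, s7$end), c(4L, 11L))

  expect_equal(nrow(scan_sites(m, strrep("G", 40))), 0L)
  expect_equal(nrow(scan_sites(m, "")), 0L)

  # DNA input equals its T->U image; N never matches
  utr_dna <- "GGGGACATTCCAGGGG"
  expect_equal(scan_sites(m, utr_dna), scan_sites(m, chartr("T", "U", utr_dna)))
  expect_equal(nrow(scan_sites(m, "GGGGACAUUCCNGGGG")),
               1L)  # 8mer broken by N, 7mer-m8 still present
  expect_equal(scan_sites(m, "GGGGACAUUCCNGGGG")$site_type, "7mer-m8")
})

test_that("scanner equals the naive substring oracle on random pairs", {
  set.seed(42)
  n_mismatch <- 0L
  for (rep in 1:60) {
    m <- rand_rna(22)
    utr <- rand_rna(500)
    # spike in a site half the time so matches are frequent
    if (rep %% 2 == 0) {
      pat <- site_patterns(m)[[sample(4, 1)]]
      pos <- sample(500 - 8, 1)
      substr(utr, pos, pos + nchar(pat) - 1) <- pat
    }
    got <- scan_sites(m, utr)[, c("start", "end", "site_type")]
    want <- naive_scan_oracle(m, utr)
    rownames(got) <- NULL
    if (!isTRUE(all.equal(got, want))) n_mismatch <- n_mismatch + 1L
  }
  expect_identical(n_mismatch, 0L)
})

test_that("reported coordinates re-slice to the pattern string", {
  set.seed(7)
  for (rep in 1:20) {
    m <- rand_rna(22)
    utr <- rand_rna(400)
    pat <- site_patterns(m)
    sites <- scan_sites(m, utr)
    if (!nrow(sites)) next
    for (i in seq_len(nrow(sites))) {
      expect_equal(substr(utr, sites$start[i] + 1, sites$end[i]),
                   unname(pat[sites$site_type[i]]))
    }
  }
})

test_that("context score combines type base, AU flanks and position", {
  # 8mer centered in a 4000-nt UTR with AU fraction 0.5 in the flanks
  flank <- strrep("AG", 15)                      # 30 nt, AU fraction 0.5
  core <- "ACAUUCCA"
  left <- strrep("C", 1996 - 30)
  utr <- paste0(left, flank, core, flank, strrep("C", 4000 - 1996 - 8 - 30))
  expect_equal(nchar(utr), 4000)
  expect_equal(context_score("8mer", 1996, 2004, utr), -0.21, tolerance = 1e-12)

  # base ordering with equal adjustments
  utr2 <- paste0(strrep("A", 30), "ACAUUCCA", strrep("A", 30))
  sc <- vapply(c("8mer", "7mer-m8", "7mer-A1", "6mer"), function(tp) {
    context_score(tp, 30, 30 + c(`8mer` = 8, `7mer-m8` = 7, `7mer-A1` = 7,
                                 `6mer` = 6)[[tp]], utr2)
  }, numeric(1))
  expect_true(all(diff(sc) > 0))  # 8mer strongest (most negative)

  # all-AU vs all-GC flanks differ by exactly w_AU at the same location
  au <- paste0(strrep("U", 30), core, strrep("A", 30))
  gc <- paste0(strrep("G", 30), core, strrep("C", 30))
  expect_equal(context_score("8mer", 30, 38, au) + 0.20,
               context_score("8mer", 30, 38, gc), tolerance = 1e-12)
})

test_that("duplex alignment matches its scoring contract and the DP oracle", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  w <- revcomp_rna(m)
  expect_equal(duplex_align(m, w, 0, nchar(w), extension = 0)$score, 145)

  # one interior non-seed WC pair changed to a mismatch: 145 - 5 - 3 = 137
  # (miRNA position 12 pairs window position 22 - 12 + 1 = 11)
  w2 <- w
  old <- substr(w2, 11, 11)
  substr(w2, 11, 11) <- c(A = "C", C = "A", G = "A", U = "C")[old]
  expect_equal(duplex_align(m, w2, 0, nchar(w2), extension = 0)$score, 137)

  # no pairing at all -> empty local alignment scores 0
  expect_equal(duplex_align(strrep("A", 22), strrep("A", 30), 0, 30,
                            extension = 0)$score, 0)

  # DP equals exhaustive enumeration on small windows
  set.seed(11)
  for (rep in 1:25) {
    mir <- rand_rna(sample(8:10, 1))
    win <- rand_rna(sample(6:12, 1))
    got <- duplex_align(mir, win, 0, nchar(win), extension = 0)$score
    mir_rev <- paste(rev(strsplit(mir, "")[[1]]), collapse = "")
    expect_equal(got, brute_force_duplex(mir_rev, win))
  }
})

test_that("window clipping at UTR bounds is not an error", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  utr <- "ACAUUCCAGG"
  d <- duplex_align(m, utr, 0, 8, extension = 25)
  expect_equal(d$window_start, 0L)
  expect_equal(d$window_end, 10L)
  expect_gt(d$score, 0)
})

test_that("percentile retention keeps the strongest tail with ties at the cut", {
  set.seed(3)
  # 100 pairs with distinct strengths -> exactly the 5 strongest retained
  sites <- data.frame(
    gene_id = sprintf("g%03d", 1:100), mirna_id = "m1",
    start = 0L, end = 8L, site_type = "8mer",
    context_score = -sample(seq(0.01, 1, length.out = 100)),
    stringsAsFactors = FALSE)
  pr <- aggregate_and_rank(sites, percentile = 95)
  expect_equal(sum(pr$retained), 5L)
  expect_true(all(pr$aggregate_score[pr$retained] <=
                    min(pr$aggregate_score[!pr$retained])))

  # identical strengths -> all retained
  sites$context_score <- -0.3
  pr2 <- aggregate_and_rank(sites, percentile = 95)
  expect_true(all(pr2$retained))

  # retained fraction bounded by (100 - percentile)/100 plus tie mass
  sites$context_score <- -round(runif(100), 1)
  pr3 <- aggregate_and_rank(sites, percentile = 90)
  cutoff <- max(pr3$aggregate_score[pr3$retained])
  tie_mass <- mean(pr3$aggregate_score == cutoff)
  expect_lte(mean(pr3$retained), 0.10 + tie_mass)
})

test_that("duplex refinement gates retention at a strict >= threshold", {
  sites <- data.frame(
    gene_id = c("g1", "g2"), mirna_id = "m1", start = 0L, end = 8L,
    site_type = "8mer", context_score = c(-0.5, -0.4),
    stringsAsFactors = FALSE)
  dup <- data.frame(mirna_id = "m1", gene_id = c("g1", "g2"),
                    duplex_score = c(80, 79), stringsAsFactors = FALSE)
  pr <- aggregate_and_rank(sites, dup, percentile = 50, refine = TRUE)
  expect_true(pr$refined[pr$gene_id == "g1"])
  expect_false(pr$refined[pr$gene_id == "g2"])
  expect_false(pr$retained[pr$gene_id == "g2"])
  expect_error(aggregate_and_rank(sites, NULL, refine = TRUE), "requires duplex")
  expect_error(aggregate_and_rank(sites, percentile = 0), "percentile")
})

test_that("6mer sites are excluded from the aggregate unless requested", {
  sites <- data.frame(
    gene_id = "g1", mirna_id = "m1", start = c(0L, 20L), end = c(8L, 26L),
    site_type = c("8mer", "6mer"), context_score = c(-0.5, -0.02),
    stringsAsFactors = FALSE)
  pr <- aggregate_and_rank(sites, percentile = 50)
  expect_equal(pr$aggregate_score, -0.5)
  expect_equal(pr$n_sites, 1L)
  pr6 <- aggregate_and_rank(sites, percentile = 50, include_6mer = TRUE)
  expect_equal(pr6$aggregate_score, -0.52)
  expect_equal(pr6$n_sites, 2L)
  # a pair with only 6mers disappears by default
  only6 <- sites[sites$site_type == "6mer", ]
  expect_equal(nrow(aggregate_and_rank(only6, percentile = 50)), 0L)
})
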