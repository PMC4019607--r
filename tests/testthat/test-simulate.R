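test_that("generators are deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 7L)
  expect_identical(gen_mirnas(cfg), gen_mirnas(cfg))
  m <- gen_mirnas(cfg)
  expect_identical(gen_utrs_with_sites(cfg, m), gen_utrs_with_sites(cfg, m))
  expect_identical(gen_expression_timecourse(cfg), gen_expression_timecourse(cfg))
  expect_identical(gen_genesets(cfg), gen_genesets(cfg))
  # different seeds give different sequences
  expect_false(identical(gen_mirnas(cfg), gen_mirnas(small_sim_config(seed = 8L))))
})

test_that("simulated files are byte-identical across runs of the same seed", {
  cfg <- small_sim_config(seed = 3L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("miRNA generation respects counts and lengths", {
  cfg <- small_sim_config()
  m <- gen_mirnas(cfg)
  expect_length(m, 10L)
  expect_true(all(nchar(m) == 22L))
  expect_false(anyDuplicated(names(m)) > 0)
  expect_true(all(grepl("^[ACGU]+$", m)))
  expect_error(simulation_config(n_mirna = 0, planted_up = numeric(0),
                                 planted_down = numeric(0),
                                 planted_sites = data.frame(),
                                 planted_links = data.frame()),
               "n_mirna")
})

test_that("planted sites are recovered at their recorded coordinates", {
  cfg <- small_sim_config(seed = 21L)
  m <- gen_mirnas(cfg)
  us <- gen_utrs_with_sites(cfg, m)
  truth <- us$true_sites
  expect_equal(nrow(truth), 4L)
  for (i in seq_len(nrow(truth))) {
    hits <- scan_sites(m[[truth$mirna_id[i]]], us$utrs[[truth$gene_id[i]]],
                       truth$mirna_id[i], truth$gene_id[i])
    j <- hits$start == truth$start[i]
    expect_true(any(j))
    expect_equal(hits$site_type[j], truth$site_type[i])
    expect_equal(hits$end[j], truth$end[i])
  }
})

test_that("clean background leaves no unplanted canonical sites", {
  cfg <- small_sim_config(seed = 5L, clean_background = "all")
  m <- gen_mirnas(cfg)
  us <- gen_utrs_with_sites(cfg, m)
  sites <- scan_all_sites(m, us$utrs)
  got <- sites[, c("mirna_id", "gene_id", "start", "end", "site_type")]
  got <- got[order(got$mirna_id, got$gene_id, got$start), ]
  want <- us$true_sites[order(us$true_sites$mirna_id, us$true_sites$gene_id,
                              us$true_sites$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  # no plants at all -> scanner finds nothing
  cfg0 <- small_sim_config(
    seed = 6L, clean_background = "all",
    planted_sites = data.frame(mirna_id = character(0), gene_id = character(0),
                               site_type = character(0)),
    planted_links = data.frame(mirna_id = character(0), gene_id = character(0),
                               sign = numeric(0), strength = numeric(0)))
  us0 <- gen_utrs_with_sites(cfg0, gen_mirnas(cfg0))
  expect_equal(nrow(scan_all_sites(gen_mirnas(cfg0), us0$utrs)), 0L)
})

test_that("noise-free expression reproduces planted folds exactly", {
  cfg <- small_sim_config(seed = 2L, noise_sigma = 0)
  ex <- gen_expression_timecourse(cfg)
  fc <- normalize_to_control(ex$expr)
  final <- fc[fc$timepoint == "d14", ]
  expect_equal(final$fc[final$entity == "mir-01"], 8)
  expect_equal(final$fc[final$entity == "mir-03"], 1 / 8)
  null_fc <- fc$fc[!fc$entity %in% c("mir-01", "mir-02", "mir-03", "mir-04")]
  expect_true(all(abs(null_fc - 1) < 1e-12))
  # monotone ramp in log space
  m1 <- fc$fc[fc$entity == "mir-01"]
  expect_true(all(diff(log(m1)) > 0))
  expect_error(small_sim_config(noise_sigma = -0.1), "noise_sigma")
})

test_that("planted anti-correlated trajectories reach r = -1 when noise-free", {
  cfg <- small_sim_config(seed = 4L, noise_sigma = 0, link_noise_sigma = 0,
                          planted_links = data.frame(
                            mirna_id = "mir-01", gene_id = "gene-01",
                            sign = -1, strength = 1))
  ex <- gen_expression_timecourse(cfg)
  tr <- gen_target_trajectories(cfg, ex$expr)
  g <- as.numeric(tr$trajectories[tr$trajectories$gene_id == "gene-01", -1])
  fcm <- normalize_to_control(ex$expr)
  x <- log2(fcm$fc[fcm$entity == "mir-01"])
  y <- log2(g[-1])  # drop control to share the non-control grid
  expect_equal(stats::cor(x, y), -1, tolerance = 1e-12)
  expect_error(small_sim_config(planted_links = data.frame(
    mirna_id = "mir-01", gene_id = "gene-01", sign = -1, strength = 1.2)),
    "strength")
})

test_that("unlinked genes are uncorrelated on average", {
  rs <- vapply(1:200, function(s) {
    cfg <- small_sim_config(seed = s, n_mirna = 4L, n_genes = 2L,
                            planted_sites = data.frame(
                              mirna_id = character(0), gene_id = character(0),
                              site_type = character(0)),
                            planted_links = data.frame(
                              mirna_id = character(0), gene_id = character(0),
                              sign = numeric(0), strength = numeric(0)))
    ex <- gen_expression_timecourse(cfg)
    tr <- gen_target_trajectories(cfg, ex$expr)
    x <- log2(as.numeric(tr$trajectories[1, -1]))
    y <- log2(as.numeric(tr$trajectories[2, -1]))
    stats::cor(x, y)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("geneset generation plants the designated overlap", {
  cfg <- small_sim_config(seed = 13L)
  gs <- gen_genesets(cfg)
  expect_length(gs$pathways, 8L)
  k <- length(intersect(gs$pathways[[gs$enriched_pathway]], gs$query_genes))
  expect_equal(k, 3L)
  # all query genes are annotated with a query term, evidence >= 1
  expect_true(all(gs$query_genes %in% gs$annotation$gene))
  expect_true(all(gs$annotation$evidence_count >= 1))
  expect_true(all(gs$annotation$term %in% default_query_terms()))

  # fraction 0 disables annotation entirely
  gs0 <- gen_genesets(small_sim_config(seed = 13L, annotated_fraction = 0))
  expect_equal(nrow(gs0$annotation), 0L)
  expect_equal(filter_by_terms(gs0$query_genes, gs0$annotation), character(0))

  expect_error(gen_genesets(small_sim_config(enriched_pathway_overlap = 30L)),
               "overlap")
})

test_that("truth sidecar is complete and consistent with the plants", {
  cfg <- small_sim_config(seed = 17L)
  sim <- simulate_dataset(cfg, NULL)
  expect_setequal(sim$truth$differential_up, names(cfg$planted_up))
  expect_setequal(sim$truth$differential_down, names(cfg$planted_down))
  expect_equal(nrow(sim$truth$true_sites), nrow(cfg$planted_sites))
  expect_equal(sim$truth$true_links[, c("mirna_id", "gene_id")],
               cfg$planted_links[, c("mirna_id", "gene_id")])
})
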