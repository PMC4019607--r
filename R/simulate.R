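# Synthetic-data generator emulating a bone-marrow culture differentiation
# time course: one uncultured-control condition plus six timepoints sampled
# every second day (d4..d14), replicate cultures, planted up-/down-regulated
# miRNAs, planted seed sites in synthetic 3'UTRs, planted anti-correlated
# target trajectories, and a pathway collection with one enriched pathway.
# Every generator is byte-identical under a fixed rng_seed and all plants are
# recorded in a ground-truth sidecar.

#' Simulation configuration
#'
#' Builds and validates the configuration shared by all generators. Defaults
#' emulate the bone-marrow culture design: an uncultured control plus six
#' culture timepoints sampled every second day, three independent cultures,
#' down-dominant planted fold changes reaching ~100-fold, and a handful of
#' planted seed sites and anti-correlated target links.
#'
#' @param rng_seed integer master seed; every generator derives its own
#'   stream from it.
#' @param n_mirna,n_genes numbers of simulated miRNAs and genes.
#' @param timepoints ordered timepoint labels, control first.
#' @param n_replicates independent cultures per timepoint.
#' @param planted_up,planted_down named numeric vectors of final fold changes
#'   (names = miRNA ids); up entries must be >= 1, down entries <= 1, and the
#'   two id sets disjoint.
#' @param noise_sigma standard deviation of the multiplicative log-normal
#'   measurement noise (natural-log scale).
#' @param utr_length UTR length in nucleotides (>= 50).
#' @param planted_sites data.frame \code{mirna_id, gene_id, site_type}.
#' @param planted_links data.frame \code{mirna_id, gene_id, sign, strength};
#'   sign in \{-1, +1\}, strength in (0, 1].
#' @param link_noise_sigma sd of the additive log2 noise on linked/unlinked
#'   gene trajectories.
#' @param n_pathways number of pathway gene sets.
#' @param enriched_pathway_overlap planted overlap between the designated
#'   pathway and the planted target genes.
#' @param pathway_size_range integer range of random pathway sizes.
#' @param annotated_fraction fraction of genes receiving a query-term
#'   annotation; 0 disables annotation entirely, otherwise the planted target
#'   genes are always included.
#' @param clean_background one of \code{"canonical"} (default: background is
#'   rejection-sampled so no unplanted 7/8-mer site of any simulated miRNA
#'   remains), \code{"all"} (also removes 6mers; feasible only for small
#'   simulations) or \code{"none"}.
#' @param baseline_range control-condition expected-signal range; baselines
#'   are drawn log-uniformly over it (fluorescence units).
#' @return validated list of class \code{mirlink_sim_config}.
#' @export
simulation_config <- function(
    rng_seed = 1L,
    n_mirna = 60L,
    n_genes = 80L,
    timepoints = c("control", "d4", "d6", "d8", "d10", "d12", "d14"),
    n_replicates = 3L,
    planted_up = stats::setNames(c(6, 8, 10, 20, 50),
                                 sprintf("mir-%02d", 1:5)),
    planted_down = stats::setNames(1 / c(6, 8, 10, 15, 20, 30, 60, 100),
                                   sprintf("mir-%02d", 6:13)),
    noise_sigma = 0.2,
    utr_length = 600L,
    planted_sites = data.frame(
      mirna_id = sprintf("mir-%02d", c(1, 2, 3, 6, 7, 8, 9, 10)),
      gene_id = sprintf("gene-%02d", 1:8),
      site_type = c("8mer", "7mer-m8", "8mer", "8mer", "7mer-A1", "8mer",
                    "7mer-m8", "8mer"),
      stringsAsFactors = FALSE),
    planted_links = data.frame(
      mirna_id = sprintf("mir-%02d", c(1, 2, 3, 6, 7, 8, 9, 10)),
      gene_id = sprintf("gene-%02d", 1:8),
      sign = -1,
      strength = 0.95,
      stringsAsFactors = FALSE),
    link_noise_sigma = 0.1,
    n_pathways = 15L,
    enriched_pathway_overlap = 6L,
    pathway_size_range = c(8L, 25L),
    annotated_fraction = 0.3,
    clean_background = c("canonical", "all", "none"),
    baseline_range = c(100, 5000)) {
  clean_background <- match.arg(clean_background)
  cfg <- list(rng_seed = as.integer(rng_seed), n_mirna = as.integer(n_mirna),
              n_genes = as.integer(n_genes), timepoints = timepoints,
              n_replicates = as.integer(n_replicates),
              planted_up = planted_up, planted_down = planted_down,
              noise_sigma = noise_sigma, utr_length = as.integer(utr_length),
              planted_sites = planted_sites, planted_links = planted_links,
              link_noise_sigma = link_noise_sigma,
              n_pathways = as.integer(n_pathways),
              enriched_pathway_overlap = as.integer(enriched_pathway_overlap),
              pathway_size_range = as.integer(pathway_size_range),
              annotated_fraction = annotated_fraction,
              clean_background = clean_background,
              baseline_range = baseline_range)
  validate_sim_config(cfg)
  structure(cfg, class = "mirlink_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_mirna < 1L) stop("n_mirna must be >= 1 (empty collection)")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (anyDuplicated(cfg$timepoints)) stop("timepoints must be unique")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cfg$utr_length < 50L) stop("utr_length must be >= 50")
  if (length(intersect(names(cfg$planted_up), names(cfg$planted_down)))) {
    stop("planted_up and planted_down must be disjoint")
  }
  if (any(c(cfg$planted_up, cfg$planted_down) <= 0)) {
    stop("all planted fold changes must be > 0")
  }
  if (length(cfg$planted_up) && any(cfg$planted_up < 1)) {
    stop("planted_up fold changes must be >= 1")
  }
  if (length(cfg$planted_down) && any(cfg$planted_down > 1)) {
    stop("planted_down fold changes must be <= 1")
  }
  if (nrow(cfg$planted_links) &&
      (any(cfg$planted_links$strength <= 0) || any(cfg$planted_links$strength > 1))) {
    stop("link strength must lie in (0, 1]")
  }
  if (nrow(cfg$planted_links) && !all(cfg$planted_links$sign %in% c(-1, 1))) {
    stop("link sign must be -1 or +1")
  }
  if (nrow(cfg$planted_sites) &&
      !all(cfg$planted_sites$site_type %in% SITE_TYPES)) {
    stop("unknown planted site type")
  }
  invisible(cfg)
}

sim_mirna_ids <- function(cfg) sprintf("mir-%02d", seq_len(cfg$n_mirna))
sim_gene_ids <- function(cfg) sprintf("gene-%02d", seq_len(cfg$n_genes))

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate mature miRNA records
#'
#' Random 22-nt RNA sequences with unique ids; deterministic under the
#' configured seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return named character vector of sequences (names = miRNA ids).
#' @export
gen_mirnas <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 1L))
  ids <- sim_mirna_ids(config)
  planted <- c(names(config$planted_up), names(config$planted_down),
               unique(config$planted_sites$mirna_id),
               unique(config$planted_links$mirna_id))
  missing <- setdiff(planted, ids)
  if (length(missing)) stop("planted miRNA ids not simulated: ",
                            paste(missing, collapse = ", "))
  stats::setNames(random_rna(config$n_mirna, 22L), ids)
}

# Raw (pre-precedence) pattern matches of a set of miRNAs in one sequence.
raw_site_matches <- function(patterns_by_mirna, seq, types) {
  hits <- list()
  for (m in names(patterns_by_mirna)) {
    pats <- patterns_by_mirna[[m]]
    for (tp in types) {
      st <- fixed_match_starts(pats[[tp]], seq)
      if (length(st)) {
        hits[[length(hits) + 1L]] <- data.frame(
          mirna_id = m, site_type = tp, start = st,
          end = st + SITE_WIDTHS[[tp]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Generate 3'UTR sequences with planted seed sites
#'
#' Each gene receives a random UTR; every planted (miRNA, gene, type) site is
#' written at a recorded, non-overlapping position. Depending on
#' \code{config$clean_background}, the background is rejection-sampled
#' (by iterative point mutation of offending windows) so that no unplanted
#' canonical site of any simulated miRNA remains: \code{"canonical"} cleans
#' 8mer and both 7mer types, \code{"all"} additionally cleans 6mers,
#' \code{"none"} leaves the background as drawn.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param mirnas named sequences from \code{\link{gen_mirnas}}.
#' @return list with \code{utrs} (named character vector) and
#'   \code{true_sites} (data.frame \code{mirna_id, gene_id, start, end,
#'   site_type}).
#' @export
gen_utrs_with_sites <- function(config, mirnas) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 2L))
  genes <- sim_gene_ids(config)
  plant <- config$planted_sites
  if (nrow(plant)) {
    if (!all(plant$gene_id %in% genes)) stop("planted gene ids not simulated")
    if (!all(plant$mirna_id %in% names(mirnas))) {
      stop("planted miRNA ids not simulated")
    }
  }
  utrs <- stats::setNames(random_rna(config$n_genes, config$utr_length), genes)

  # place planted sites at non-overlapping random positions
  truth <- list()
  planted_windows <- stats::setNames(vector("list", length(genes)), genes)
  if (nrow(plant)) {
    for (g in unique(plant$gene_id)) {
      rows <- plant[plant$gene_id == g, , drop = FALSE]
      occupied <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nrow(rows))) {
        w <- SITE_WIDTHS[[rows$site_type[i]]]
        cand <- sample(0:(config$utr_length - w))
        pos <- NA_integer_
        for (p in cand) {
          if (!nrow(occupied) ||
              !any(p < occupied[, 2] & (p + w) > occupied[, 1])) {
            pos <- p; break
          }
        }
        if (is.na(pos)) stop("cannot place planted site without overlap for ", g)
        occupied <- rbind(occupied, c(pos, pos + w))
        pat <- site_patterns(mirnas[[rows$mirna_id[i]]])[[rows$site_type[i]]]
        substr(utrs[[g]], pos + 1L, pos + w) <- pat
        truth[[length(truth) + 1L]] <- data.frame(
          mirna_id = rows$mirna_id[i], gene_id = g, start = pos,
          end = pos + w, site_type = rows$site_type[i],
          stringsAsFactors = FALSE)
        planted_windows[[g]] <- rbind(
          planted_windows[[g]],
          data.frame(mirna_id = rows$mirna_id[i], start = pos, end = pos + w,
                     stringsAsFactors = FALSE))
      }
    }
  }
  true_sites <- if (length(truth)) do.call(rbind, truth) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               start = integer(0), end = integer(0), site_type = character(0),
               stringsAsFactors = FALSE)

  if (config$clean_background != "none") {
    types <- if (config$clean_background == "all") SITE_TYPES else
      c("8mer", "7mer-m8", "7mer-A1")
    pats <- lapply(mirnas, site_patterns)
    for (g in genes) {
      pw <- planted_windows[[g]]
      for (iter in seq_len(500L)) {
        hits <- raw_site_matches(pats, utrs[[g]], types)
        offending <- NULL
        if (!is.null(hits)) {
          ok <- vapply(seq_len(nrow(hits)), function(i) {
            !is.null(pw) && any(pw$mirna_id == hits$mirna_id[i] &
                                hits$start[i] >= pw$start &
                                hits$end[i] <= pw$end)
          }, logical(1))
          offending <- hits[!ok, , drop = FALSE]
        }
        if (is.null(offending) || !nrow(offending)) break
        if (iter == 500L) stop("clean background unattainable for ", g)
        for (i in seq_len(nrow(offending))) {
          span <- offending$start[i]:(offending$end[i] - 1L)
          if (!is.null(pw) && nrow(pw)) {
            covered <- vapply(span, function(p) {
              any(p >= pw$start & p < pw$end)
            }, logical(1))
            span <- span[!covered]
          }
          if (!length(span)) stop("offending background site overlaps a planted window in ", g)
          p <- span[sample.int(length(span), 1L)]
          old <- substr(utrs[[g]], p + 1L, p + 1L)
          substr(utrs[[g]], p + 1L, p + 1L) <-
            sample(setdiff(c("A", "C", "G", "U"), old), 1L)
        }
      }
    }
  }
  list(utrs = utrs, true_sites = true_sites)
}

#' Generate the miRNA expression time course
#'
#' Control-condition expected values are drawn log-uniformly over
#' \code{baseline_range}. A planted miRNA ramps monotonically in log space
#' from its baseline to \code{baseline * fold} at the final timepoint;
#' non-planted miRNAs are flat. Each replicate measurement is multiplied by
#' \code{exp(N(0, noise_sigma^2))}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{expr} (a \code{mirlink_expr}) and ground-truth id
#'   sets \code{differential_up}, \code{differential_down}.
#' @export
gen_expression_timecourse <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 3L))
  ids <- sim_mirna_ids(config)
  tps <- config$timepoints
  n_tp <- length(tps)
  base <- 10^stats::runif(config$n_mirna, log10(config$baseline_range[1]),
                          log10(config$baseline_range[2]))
  names(base) <- ids
  folds <- stats::setNames(rep(1, config$n_mirna), ids)
  folds[names(config$planted_up)] <- config$planted_up
  folds[names(config$planted_down)] <- config$planted_down
  frac <- (seq_len(n_tp) - 1) / (n_tp - 1)   # 0 at control, 1 at final
  expected <- outer(base, rep(1, n_tp)) * outer(folds, frac, `^`)
  cols <- as.vector(t(outer(tps, seq_len(config$n_replicates),
                            function(tp, r) paste0(tp, "_r", r))))
  vals <- matrix(NA_real_, config$n_mirna, length(cols),
                 dimnames = list(ids, cols))
  for (j in seq_len(n_tp)) {
    for (r in seq_len(config$n_replicates)) {
      noise <- exp(stats::rnorm(config$n_mirna, 0, config$noise_sigma))
      vals[, paste0(tps[j], "_r", r)] <- expected[, j] * noise
    }
  }
  list(expr = expression_matrix(vals, control_label = tps[1]),
       differential_up = sort(names(config$planted_up)),
       differential_down = sort(names(config$planted_down)))
}

#' Generate target-gene trajectories tied to miRNA profiles
#'
#' For each planted link the gene's log2 trajectory is
#' \code{sign * strength * z + noise}, where \code{z} is the standardized
#' log2 miRNA trajectory (timepoint means) and noise is
#' \code{N(0, link_noise_sigma^2)} per timepoint; unlinked genes get
#' independent standard-normal log2 noise. Values are returned as positive
#' relative-expression numbers (\code{2^log2}) on the same timepoint grid.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param expr the expression object from
#'   \code{\link{gen_expression_timecourse}}.
#' @return list with \code{trajectories} (data.frame, \code{gene_id} +
#'   one column per timepoint) and \code{true_links} (the planted link table).
#' @export
gen_target_trajectories <- function(config, expr) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 4L))
  tps <- config$timepoints
  means <- timepoint_means(expr, "arithmetic")
  genes <- sim_gene_ids(config)
  links <- config$planted_links
  if (nrow(links)) {
    if (!all(links$mirna_id %in% rownames(means))) {
      stop("planted link miRNA ids not simulated")
    }
    if (!all(links$gene_id %in% genes)) stop("planted link gene ids not simulated")
  }
  traj <- matrix(NA_real_, length(genes), length(tps),
                 dimnames = list(genes, tps))
  for (g in genes) {
    row <- links[links$gene_id == g, , drop = FALSE]
    if (nrow(row)) {
      lm2 <- log2(means[row$mirna_id[1], tps])
      if (stats::sd(lm2) == 0) {
        stop("linked miRNA ", row$mirna_id[1], " has a constant trajectory")
      }
      z <- (lm2 - mean(lm2)) / stats::sd(lm2)
      traj[g, ] <- row$sign[1] * row$strength[1] * z +
        stats::rnorm(length(tps), 0, config$link_noise_sigma)
    } else {
      traj[g, ] <- stats::rnorm(length(tps), 0, 1)
    }
  }
  out <- data.frame(gene_id = genes, 2^traj, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(trajectories = out, true_links = links)
}

#' Generate the annotation map and pathway collection
#'
#' One designated pathway receives \code{enriched_pathway_overlap} planted
#' target genes; remaining pathway memberships are random over the background
#' (non-planted) genes, so the planted pathway is the only one enriched for
#' the target set and the simulation is a clean positive control. The annotation map assigns query terms (evidence >= 1) to the
#' planted target genes plus a random fill up to
#' \code{annotated_fraction * n_genes}; a fraction of 0 yields an empty map.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list \code{annotation} (data.frame), \code{pathways} (named list),
#'   \code{enriched_pathway} (its name), \code{query_genes} (the planted
#'   target genes).
#' @export
gen_genesets <- function(config) {
  validate_sim_config(config)
  if (config$n_pathways < 1L) stop("n_pathways must be >= 1")
  set.seed(derive_seed(config$rng_seed, 5L))
  genes <- sim_gene_ids(config)
  query <- sort(unique(c(config$planted_sites$gene_id,
                         config$planted_links$gene_id)))
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  if (config$enriched_pathway_overlap > sizes[1]) {
    stop("enriched overlap exceeds the designated pathway's size")
  }
  if (config$enriched_pathway_overlap > length(query)) {
    stop("enriched overlap exceeds the planted query-set size")
  }
  pw_names <- sprintf("pathway_%02d", seq_len(config$n_pathways))
  pathways <- vector("list", config$n_pathways)
  names(pathways) <- pw_names
  overlap_genes <- sample(query, config$enriched_pathway_overlap)
  fill <- sample(setdiff(genes, overlap_genes),
                 sizes[1] - config$enriched_pathway_overlap)
  pathways[[1]] <- sort(c(overlap_genes, fill))
  background <- setdiff(genes, query)
  for (i in seq_len(config$n_pathways)[-1]) {
    if (sizes[i] > length(background)) {
      stop("pathway size exceeds the background gene pool")
    }
    pathways[[i]] <- sort(sample(background, sizes[i]))
  }
  if (config$annotated_fraction == 0) {
    annotation <- data.frame(gene = character(0), term = character(0),
                             evidence_count = integer(0),
                             stringsAsFactors = FALSE)
  } else {
    n_annot <- max(length(query),
                   round(config$annotated_fraction * config$n_genes))
    extra <- sample(setdiff(genes, query), max(0L, n_annot - length(query)))
    annotated <- c(query, extra)
    terms <- default_query_terms()
    annotation <- data.frame(
      gene = annotated,
      term = sample(terms, length(annotated), replace = TRUE),
      evidence_count = sample(1:5, length(annotated), replace = TRUE),
      stringsAsFactors = FALSE)
    annotation <- annotation[order(annotation$gene), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  list(annotation = annotation, pathways = pathways,
       enriched_pathway = pw_names[1], query_genes = query)
}

#' Simulate a complete dataset and write all pipeline inputs
#'
#' Runs every generator and writes: \code{mirnas.fasta}, \code{utrs.fasta},
#' \code{expression.tsv}, \code{trajectories.tsv}, \code{annotation.tsv},
#' \code{pathways.gmt} and the ground-truth sidecar \code{truth.json}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param outdir output directory (created if missing); NULL to skip writing.
#' @return list with all generated objects, the \code{truth} sidecar and the
#'   written \code{paths}.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  mirnas <- gen_mirnas(config)
  us <- gen_utrs_with_sites(config, mirnas)
  ex <- gen_expression_timecourse(config)
  tr <- gen_target_trajectories(config, ex$expr)
  gs <- gen_genesets(config)
  truth <- list(differential_up = ex$differential_up,
                differential_down = ex$differential_down,
                true_sites = us$true_sites,
                true_links = tr$true_links,
                enriched_pathway = gs$enriched_pathway,
                query_genes = gs$query_genes)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      mirnas = file.path(outdir, "mirnas.fasta"),
      utrs = file.path(outdir, "utrs.fasta"),
      expression = file.path(outdir, "expression.tsv"),
      trajectories = file.path(outdir, "trajectories.tsv"),
      annotation = file.path(outdir, "annotation.tsv"),
      pathways = file.path(outdir, "pathways.gmt"),
      truth = file.path(outdir, "truth.json"))
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(mirnas), paths$mirnas)
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(us$utrs), paths$utrs)
    expr_df <- data.frame(mirna_id = rownames(ex$expr$values),
                          ex$expr$values, check.names = FALSE,
                          stringsAsFactors = FALSE)
    write_tsv_plain(expr_df, paths$expression)
    write_tsv_plain(tr$trajectories, paths$trajectories)
    write_tsv_plain(gs$annotation, paths$annotation)
    write_gmt(gs$pathways, paths$pathways)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  list(config = config, mirnas = mirnas, utrs = us$utrs, expr = ex$expr,
       trajectories = tr$trajectories, annotation = gs$annotation,
       pathways = gs$pathways, truth = truth, paths = paths)
}
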