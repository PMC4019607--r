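# Config-driven orchestration: normalize -> select -> scan -> refine -> rank
# -> annotate-filter -> enrich -> link -> export, with a machine-readable run
# manifest. Any stage error aborts with the stage name attached.

#' Build and validate a pipeline configuration
#'
#' All thresholds default to the workflow's standard constants: 5-fold
#' selection, 95th-percentile target retention, duplex refinement threshold
#' 80, Pearson gate at alpha 0.05, top 30 pathways.
#'
#' @param expression,mirnas,utrs,annotation,pathways,trajectories input file
#'   paths (expression TSV, miRNA FASTA, UTR FASTA, annotation TSV, GMT,
#'   trajectory TSV).
#' @param outdir output directory.
#' @param control_label control timepoint label in the expression table.
#' @param fold_threshold differential fold-change threshold (> 1).
#' @param percentile target retention percentile in (0, 100).
#' @param duplex_threshold minimum best duplex score when refining.
#' @param alpha Pearson gate significance level in (0, 1).
#' @param terms annotation query terms.
#' @param min_evidence minimum annotation evidence count.
#' @param top_k pathways reported.
#' @param rng_seed seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters when the inputs are simulated).
#' @param refine,include_6mer,per_mirna_percentile,bh_adjust,negative_only,endpoint_only
#'   stage flags, see the stage functions.
#' @param floor normalization signal floor.
#' @param combine replicate summary (\code{"arithmetic"}/\code{"geometric"}).
#' @param log2_scale correlate log2 trajectories.
#' @param extension duplex window extension (nt).
#' @return validated list of class \code{mirlink_config}.
#' @export
pipeline_config <- function(expression, mirnas, utrs, annotation, pathways,
                            trajectories, outdir,
                            control_label = "control", fold_threshold = 5,
                            percentile = 95, duplex_threshold = 80,
                            alpha = 0.05, terms = default_query_terms(),
                            min_evidence = 1L, top_k = 30L, rng_seed = 1L,
                            refine = TRUE, include_6mer = FALSE,
                            per_mirna_percentile = FALSE, bh_adjust = FALSE,
                            negative_only = TRUE, endpoint_only = FALSE,
                            floor = 1.0, combine = "arithmetic",
                            log2_scale = TRUE, extension = 25L) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "mirlink_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (cfg$percentile <= 0 || cfg$percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$top_k < 1) stop("top_k must be >= 1")
  if (cfg$floor <= 0) stop("floor must be > 0")
  if (!cfg$combine %in% c("arithmetic", "geometric")) {
    stop("combine must be 'arithmetic' or 'geometric'")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. CLI flags).
#' @return \code{mirlink_config} object.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

read_fasta_named <- function(path) {
  x <- Biostrings::readBStringSet(path)
  as_rna(stats::setNames(as.character(x), names(x)))
}

# named per-timepoint trajectory vectors from a trajectory TSV data.frame
traj_list <- function(df) {
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  stats::setNames(lapply(seq_len(nrow(vals)), function(i) {
    stats::setNames(vals[i, ], colnames(vals))
  }), ids)
}

#' Run the full link-prediction pipeline
#'
#' Executes all stages in order and writes every intermediate and final table
#' under \code{config$outdir}: \code{fold_changes.tsv}, \code{calls.tsv},
#' \code{sites.tsv}, \code{predictions.tsv}, \code{filtered_genes.txt},
#' \code{enrichment.tsv}, \code{enrichment_summary.json}, \code{edges.tsv},
#' \code{network.graphml} and \code{manifest.json}. Output bytes are
#' deterministic for fixed inputs and configuration (the manifest records
#' wall-clock times and is the only non-reproducible file).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the run manifest (invisibly written to \code{manifest.json}):
#'   config echo + hash, input checksums, per-stage row counts, elapsed
#'   seconds, package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirlink_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  log_stage <- function(name, n) {
    counts[[name]] <<- n
    message("[", name, "] ", n, " rows")
  }

  expr <- run_stage("read", read_expression_table(config$expression,
                                                  config$control_label))
  profiles <- run_stage("normalize",
                        normalize_to_control(expr, floor = config$floor,
                                             combine = config$combine))
  log_stage("normalize", nrow(profiles))
  calls <- run_stage("select",
                     select_differential(profiles, config$fold_threshold,
                                         endpoint_only = config$endpoint_only))
  log_stage("select", nrow(calls))

  mirnas <- run_stage("read", read_fasta_named(config$mirnas))
  utrs <- run_stage("read", read_fasta_named(config$utrs))
  selected <- intersect(calls$entity, names(mirnas))
  pred <- run_stage("scan_rank",
                    predict_targets(mirnas[selected], utrs,
                                    percentile = config$percentile,
                                    refine = config$refine,
                                    duplex_threshold = config$duplex_threshold,
                                    include_6mer = config$include_6mer,
                                    per_mirna = config$per_mirna_percentile,
                                    extension = config$extension))
  log_stage("sites", nrow(pred$sites))
  log_stage("predictions_retained", sum(pred$predictions$retained))

  retained <- pred$predictions[pred$predictions$retained, , drop = FALSE]
  predicted_genes <- sort(unique(retained$gene_id))
  annotation <- run_stage("read", read_annotation_map(config$annotation))
  annotated <- run_stage("annotate",
                         filter_by_terms(predicted_genes, annotation,
                                         terms = config$terms,
                                         min_evidence = config$min_evidence))
  filtered <- intersect_targets(predicted_genes, annotated)
  log_stage("filtered_genes", length(filtered))

  pathways <- run_stage("read", read_gmt(config$pathways))
  enr <- run_stage("enrich",
                   enrich_pathways(filtered, pathways, top_k = config$top_k,
                                   adjust = if (config$bh_adjust) "BH" else "none"))
  summ <- enrichment_summary(filtered, enr, pathways)
  log_stage("enrichment", nrow(enr))

  traj_df <- run_stage("read", read_tsv_plain(config$trajectories))
  gene_trajs <- traj_list(traj_df)
  fc_wide <- split(profiles, profiles$entity)
  mirna_trajs <- lapply(fc_wide, function(p) {
    stats::setNames(p$fc, as.character(p$timepoint))
  })
  link_preds <- retained[retained$gene_id %in% filtered, , drop = FALSE]
  edges <- run_stage("link",
                     predict_links(mirna_trajs, gene_trajs, link_preds,
                                   alpha = config$alpha,
                                   mode = if (config$negative_only) "negative" else "any",
                                   calls = calls,
                                   log2_scale = config$log2_scale))
  log_stage("edges", nrow(edges))

  # outputs
  fc_wide_df <- stats::reshape(
    profiles[, c("entity", "timepoint", "fc")],
    idvar = "entity", timevar = "timepoint", direction = "wide")
  names(fc_wide_df) <- sub("^fc\\.", "fc_", names(fc_wide_df))
  out <- function(f) file.path(config$outdir, f)
  write_tsv_plain(fc_wide_df, out("fold_changes.tsv"))
  write_tsv_plain(calls, out("calls.tsv"))
  write_tsv_plain(pred$sites, out("sites.tsv"))
  write_tsv_plain(pred$predictions, out("predictions.tsv"))
  writeLines(filtered, out("filtered_genes.txt"))
  write_tsv_plain(enr, out("enrichment.tsv"))
  jsonlite::write_json(summ, out("enrichment_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  export_network(edges, out("edges.tsv"), out("network.graphml"))

  cfg_plain <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  inputs <- unlist(cfg_plain[c("expression", "mirnas", "utrs", "annotation",
                               "pathways", "trajectories")])
  manifest <- list(
    config = cfg_plain,
    config_hash = cfg_hash,
    input_md5 = as.list(tools::md5sum(inputs)),
    stage_counts = counts,
    n_up = sum(calls$direction == "up"),
    n_down = sum(calls$direction == "down"),
    covered_pct = summ$covered_pct,
    elapsed_sec = proc.time()[["elapsed"]] - t0,
    version = as.character(utils::packageVersion("mirlink")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
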