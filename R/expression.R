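# Expression stage: parse the condition-by-entity matrix, normalize each
# entity to the uncultured control condition, call >= threshold-fold
# trajectories, and compute qPCR relative expression (2^-ddCt).

#' Read an expression table
#'
#' Expects a TSV whose first column holds unique entity ids and whose
#' remaining column names are condition labels of the form
#' \code{<timepoint>_r<replicate>} (e.g. \code{d4_r1}); one timepoint is the
#' designated control.
#'
#' @param path TSV file path.
#' @param control_label timepoint label of the control condition.
#' @return object of class \code{mirlink_expr}: list with \code{values}
#'   (numeric matrix, rows = entities), \code{conditions} (data.frame with
#'   \code{label}, \code{timepoint}, \code{replicate}), \code{control_label},
#'   and \code{timepoints} (ordered, control first).
#' @export
read_expression_table <- function(path, control_label = "control") {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2L) stop("expression table needs an id column plus conditions")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate entity ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (nrow(vals) == 0L) warning("expression table has a header but no rows")
  if (any(vals < 0, na.rm = TRUE)) stop("negative expression values are not allowed")
  expression_matrix(vals, control_label = control_label)
}

#' Construct an expression matrix object from a numeric matrix
#'
#' @param values numeric matrix, rows = entity ids, columns named
#'   \code{<timepoint>_r<replicate>}.
#' @param control_label the control timepoint label; must be present.
#' @return \code{mirlink_expr} object, see \code{\link{read_expression_table}}.
#' @export
expression_matrix <- function(values, control_label = "control") {
  conds <- split_condition_labels(colnames(values))
  if (!control_label %in% conds$timepoint) {
    stop("control timepoint '", control_label, "' absent from columns")
  }
  tps <- unique(conds$timepoint)
  tps <- c(control_label, setdiff(tps, control_label))
  structure(list(values = values, conditions = conds,
                 control_label = control_label, timepoints = tps),
            class = "mirlink_expr")
}

#' @export
print.mirlink_expr <- function(x, ...) {
  cat("mirlink expression matrix:", nrow(x$values), "entities x",
      ncol(x$values), "conditions\n")
  cat("timepoints:", paste(x$timepoints, collapse = ", "),
      "(control:", paste0(x$control_label, ")\n"))
  invisible(x)
}

# Per-entity, per-timepoint replicate summary (arithmetic or geometric mean).
timepoint_means <- function(expr, combine = c("arithmetic", "geometric")) {
  combine <- match.arg(combine)
  vapply(expr$timepoints, function(tp) {
    cols <- expr$conditions$label[expr$conditions$timepoint == tp]
    sub <- expr$values[, cols, drop = FALSE]
    if (combine == "arithmetic") rowMeans(sub, na.rm = TRUE)
    else exp(rowMeans(log(sub), na.rm = TRUE))
  }, numeric(nrow(expr$values)))
}

#' Normalize each entity to the control condition
#'
#' For every non-control timepoint t the fold change is
#' \code{FC_t = max(mean_t, floor) / max(mean_control, floor)}; replicate
#' values are combined by the arithmetic mean of the raw signal by default.
#' The floor keeps log2 fold changes finite for zero/low signal.
#'
#' @param expr a \code{mirlink_expr} object.
#' @param floor positive signal floor (default 1.0 fluorescence unit).
#' @param combine replicate summary: \code{"arithmetic"} (default) or
#'   \code{"geometric"} mean.
#' @return long-format data.frame with columns \code{entity}, \code{timepoint}
#'   (non-control, in axis order), \code{fc}, \code{log2_fc}. Entities whose
#'   control replicates are all missing are dropped with a warning.
#' @export
normalize_to_control <- function(expr, floor = 1.0,
                                 combine = c("arithmetic", "geometric")) {
  stopifnot(inherits(expr, "mirlink_expr"), floor > 0)
  means <- timepoint_means(expr, combine)
  ctrl <- means[, expr$control_label]
  drop <- !is.finite(ctrl)
  if (any(drop)) {
    warning(sum(drop), " entit(ies) dropped: all control replicates missing")
    means <- means[!drop, , drop = FALSE]
    ctrl <- ctrl[!drop]
  }
  tps <- setdiff(expr$timepoints, expr$control_label)
  ids <- rownames(means)
  out <- do.call(rbind, lapply(tps, function(tp) {
    fc <- pmax(means[, tp], floor) / pmax(ctrl, floor)
    data.frame(entity = ids, timepoint = tp, fc = unname(fc),
               log2_fc = unname(log2(fc)), stringsAsFactors = FALSE)
  }))
  out$timepoint <- factor(out$timepoint, levels = tps)
  out[order(out$entity, out$timepoint), c("entity", "timepoint", "fc", "log2_fc")]
}

#' Call differential trajectories at a fold-change threshold
#'
#' An entity is called up if any timepoint's fold change is \code{>=
#' threshold} and down if any is \code{<= 1/threshold} (inclusive
#' comparisons). If both occur, the direction with the larger |log2 FC| wins;
#' an exact tie is classified up and flagged ambiguous. With
#' \code{endpoint_only = TRUE} only the final timepoint is examined.
#'
#' @param profiles fold-change table from \code{\link{normalize_to_control}}.
#' @param threshold fold-change threshold, must exceed 1 (default 5).
#' @param endpoint_only restrict the test to the last timepoint.
#' @return data.frame with \code{entity}, \code{direction} (\code{"up"} /
#'   \code{"down"}), \code{extreme_fc}, \code{extreme_timepoint},
#'   \code{threshold}, \code{ambiguous}; ordered by entity id.
#' @export
select_differential <- function(profiles, threshold = 5, endpoint_only = FALSE) {
  if (threshold <= 1) stop("threshold must be > 1")
  if (endpoint_only) {
    last_tp <- utils::tail(levels(factor(profiles$timepoint)), 1L)
    profiles <- profiles[as.character(profiles$timepoint) == last_tp, , drop = FALSE]
  }
  calls <- lapply(split(profiles, profiles$entity), function(p) {
    i_max <- which.max(p$fc); i_min <- which.min(p$fc)
    up <- p$fc[i_max] >= threshold
    down <- p$fc[i_min] <= 1 / threshold
    if (!up && !down) return(NULL)
    ambiguous <- FALSE
    if (up && down) {
      lu <- abs(log2(p$fc[i_max])); ld <- abs(log2(p$fc[i_min]))
      if (lu == ld) ambiguous <- TRUE
      if (ld > lu) up <- FALSE else down <- FALSE
    }
    i <- if (up) i_max else i_min
    data.frame(entity = p$entity[1], direction = if (up) "up" else "down",
               extreme_fc = p$fc[i],
               extreme_timepoint = as.character(p$timepoint[i]),
               threshold = threshold, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    calls <- data.frame(entity = character(0), direction = character(0),
                        extreme_fc = numeric(0), extreme_timepoint = character(0),
                        threshold = numeric(0), ambiguous = logical(0),
                        stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$entity), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Count up/down differential calls
#'
#' @param calls table from \code{\link{select_differential}}.
#' @return named list \code{n_up}, \code{n_down}, \code{n_total}.
#' @export
summarize_directions <- function(calls) {
  list(n_up = sum(calls$direction == "up"),
       n_down = sum(calls$direction == "down"),
       n_total = nrow(calls))
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (gene, sample) first; then
#' \code{dCt(g, s) = Ct(g, s) - Ct(hk, s)},
#' \code{ddCt = dCt(g, s) - dCt(g, ref)}, and relative expression is
#' \code{2^-ddCt} (1.0 for the reference sample by construction).
#'
#' @param ct data.frame with columns \code{gene}, \code{sample}, \code{ct}
#'   (PCR cycle numbers; replicate rows allowed).
#' @param housekeeping housekeeping gene id, present for every sample.
#' @param reference reference sample id.
#' @return data.frame \code{gene}, \code{sample}, \code{rel_expr} for all
#'   non-housekeeping genes.
#' @export
relative_expression_ddct <- function(ct, housekeeping, reference) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct values")
  mean_ct <- stats::aggregate(ct ~ gene + sample, data = ct, FUN = mean)
  samples <- unique(mean_ct$sample)
  hk <- mean_ct[mean_ct$gene == housekeeping, , drop = FALSE]
  missing_hk <- setdiff(samples, hk$sample)
  if (length(missing_hk)) {
    stop("housekeeping Ct missing for sample(s): ",
         paste(missing_hk, collapse = ", "))
  }
  if (!reference %in% samples) stop("reference sample '", reference, "' absent")
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  tgt <- mean_ct[mean_ct$gene != housekeeping, , drop = FALSE]
  tgt$dct <- tgt$ct - hk_ct[tgt$sample]
  ref_dct <- stats::setNames(tgt$dct[tgt$sample == reference],
                             tgt$gene[tgt$sample == reference])
  no_ref <- setdiff(unique(tgt$gene), names(ref_dct))
  if (length(no_ref)) {
    stop("reference-sample Ct missing for gene(s): ", paste(no_ref, collapse = ", "))
  }
  tgt$rel_expr <- 2^(-(tgt$dct - ref_dct[tgt$gene]))
  out <- tgt[order(tgt$gene, tgt$sample), c("gene", "sample", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' Reproduce the headline differential-selection counts from a deposited matrix
#'
#' Runs the full selection chain (control normalization with the default
#' floor, inclusive 5-fold trajectory filter, direction summary) on a local
#' copy of a processed miRNA expression matrix in the package's TSV layout.
#' Intended for checking the pipeline against externally deposited time-course
#' data, which must be downloaded and exported to TSV by the user; no network
#' access is attempted.
#'
#' @param path local TSV path (entity id column + \code{<timepoint>_r<k>}
#'   condition columns including a control timepoint).
#' @param control_label control timepoint label.
#' @param threshold fold-change threshold (default 5).
#' @return list \code{n_up}, \code{n_down}, \code{n_total}.
#' @export
reproduce_headline_selection <- function(path, control_label = "control",
                                         threshold = 5) {
  if (!file.exists(path)) {
    stop("deposited expression matrix not found at '", path,
         "'; download the accession's processed matrix and export it to the ",
         "package TSV layout first")
  }
  expr <- read_expression_table(path, control_label = control_label)
  summarize_directions(select_differential(normalize_to_control(expr),
                                           threshold = threshold))
}
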