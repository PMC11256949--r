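# Evaluation protocol: coefficient of determination and explained
# variance over all genes and over top differentially expressed genes,
# with the single-cell mean-profile aggregation.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the mean of `actual`.
#' This is the regression r2 (it can be negative), not squared Pearson
#' correlation.  A constant `actual` makes the metric undefined: `NA` is
#' returned with a warning and such entries are excluded from summaries.
#'
#' @param pred,actual numeric vectors of equal length (>= 2).
#' @return scalar, at most 1.
#' @export
r2_score <- function(pred, actual) {
  if (length(pred) != length(actual) || length(actual) < 2L)
    pc_stop("pred and actual must have equal length >= 2", "pertcycle_shape_error")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    warning("constant actual vector: r2 undefined, returning NA")
    return(NA_real_)
  }
  1 - sum((actual - pred)^2) / ss_tot
}

#' Explained variance
#'
#' `1 - Var(actual - pred) / Var(actual)`.  Unlike [r2_score()], a
#' constant prediction bias does not reduce the score.
#'
#' @inheritParams r2_score
#' @export
explained_variance <- function(pred, actual) {
  if (length(pred) != length(actual) || length(actual) < 2L)
    pc_stop("pred and actual must have equal length >= 2", "pertcycle_shape_error")
  v <- stats::var(actual)
  if (v == 0) {
    warning("constant actual vector: explained variance undefined, returning NA")
    return(NA_real_)
  }
  1 - stats::var(actual - pred) / v
}

#' Select top differentially expressed genes
#'
#' Genes with `|log2 fold change| >= threshold` between treated and
#' control mean profiles, ranked by `|log2 fc|` descending and truncated
#' to `n`; ties break by gene index ascending.  May return fewer than `n`
#' genes.  For nonnegative expression, fold change uses a pseudocount
#' `log2((treated + eps) / (control + eps))`; with `log_space = TRUE` the
#' values are taken as already log-scale and the fold change is simply the
#' difference of means `treated - control`.
#'
#' @param control_mean,treated_mean per-gene mean expression vectors.
#' @param n maximum number of genes (default 50).
#' @param threshold minimum `|log2 fc|` (default 1).
#' @param log_space values are already log-scale; fold change is the
#'   difference of means.
#' @param pseudocount eps for the ratio convention.
#' @return integer vector of gene indices, ordered by effect size.
#' @export
select_top_degs <- function(control_mean, treated_mean, n = 50L,
                            threshold = 1, log_space = FALSE,
                            pseudocount = 1e-2) {
  if (length(control_mean) != length(treated_mean))
    pc_stop("mean vectors must have equal length", "pertcycle_shape_error")
  if (!log_space && any(control_mean + pseudocount <= 0 |
                        treated_mean + pseudocount <= 0))
    pc_stop("nonpositive means under the ratio convention; use log_space = TRUE",
            "pertcycle_config_error")
  fc <- if (log_space) treated_mean - control_mean
        else log2((treated_mean + pseudocount) / (control_mean + pseudocount))
  hits <- which(abs(fc) >= threshold)
  if (!length(hits)) return(integer())
  ord <- hits[order(-abs(fc[hits]), hits)]
  utils::head(ord, n)
}

summarize_report <- function(per_condition) {
  metrics <- c("r2_all", "ev_all", "r2_deg", "ev_deg")
  summary <- do.call(rbind, lapply(metrics, function(mt) {
    v <- per_condition[[mt]]
    data.frame(metric = mt,
               mean = mean(v, na.rm = TRUE),
               median = stats::median(v, na.rm = TRUE),
               n = sum(!is.na(v)))
  }))
  list(per_condition = per_condition, summary = summary)
}

condition_key <- function(records) {
  paste(records$perturbation_id, records$context_id, sep = "|")
}

#' Evaluate single-cell predictions by mean-profile agreement
#'
#' For each (perturbation, context) condition, predicted and actual cells
#' are averaged per gene and r2 / explained variance are computed between
#' the two mean profiles, over all genes and over the condition's top
#' differentially expressed genes.  DEGs always come from the actual data
#' (actual control means vs actual treated means), never from
#' predictions.
#'
#' @param pred an [expression_dataset()] of predicted treated cells.
#' @param actual an [expression_dataset()] with actual treated cells and
#'   the control cells used for the DEG reference.
#' @param n_degs,deg_threshold,log_space forwarded to [select_top_degs()].
#' @return list with `per_condition` data frame and `summary`.
#' @export
evaluate_single_cell <- function(pred, actual, n_degs = 50L,
                                 deg_threshold = 1, log_space = FALSE) {
  act_ctrl <- actual$records$kind == "control"
  if (!any(act_ctrl))
    pc_stop("actual dataset has no control cells for the DEG reference",
            "pertcycle_config_error")
  control_mean <- colMeans(actual$matrix[act_ctrl, , drop = FALSE])
  pk <- condition_key(pred$records[pred$records$kind != "control", , drop = FALSE])
  pred_treated <- pred$matrix[pred$records$kind != "control", , drop = FALSE]
  ak <- condition_key(actual$records[!act_ctrl, , drop = FALSE])
  act_treated <- actual$matrix[!act_ctrl, , drop = FALSE]
  conds <- intersect(unique(ak), unique(pk))
  skipped <- setdiff(union(unique(ak), unique(pk)), conds)
  if (length(skipped))
    warning(sprintf("condition(s) missing from one side, skipped: %s",
                    paste(skipped, collapse = ", ")))
  rows <- lapply(conds, function(cd) {
    pm <- colMeans(pred_treated[pk == cd, , drop = FALSE])
    am <- colMeans(act_treated[ak == cd, , drop = FALSE])
    degs <- select_top_degs(control_mean, am, n_degs, deg_threshold, log_space)
    parts <- strsplit(cd, "|", fixed = TRUE)[[1]]
    data.frame(perturbation_id = parts[1],
               context_id = parts[2],
               r2_all = r2_score(pm, am),
               ev_all = explained_variance(pm, am),
               r2_deg = if (length(degs) >= 2L) r2_score(pm[degs], am[degs]) else NA_real_,
               ev_deg = if (length(degs) >= 2L) explained_variance(pm[degs], am[degs]) else NA_real_,
               n_degs = length(degs),
               n_cells = sum(ak == cd))
  })
  summarize_report(do.call(rbind, rows))
}

#' Evaluate paired predictions sample by sample
#'
#' Bulk protocol: r2 / explained variance per sample (matched by
#' `sample_id`) without cell averaging, aggregated per condition and
#' overall.  The DEG subset per condition comes from actual control vs
#' actual treated means, as in [evaluate_single_cell()].
#'
#' @inheritParams evaluate_single_cell
#' @return list with `per_sample`, `per_condition` and `summary`.
#' @export
evaluate_paired <- function(pred, actual, n_degs = 50L, deg_threshold = 1,
                            log_space = FALSE) {
  act_ctrl <- actual$records$kind == "control"
  if (!any(act_ctrl))
    pc_stop("actual dataset has no control samples for the DEG reference",
            "pertcycle_config_error")
  control_mean <- colMeans(actual$matrix[act_ctrl, , drop = FALSE])
  a_rec <- actual$records[!act_ctrl, , drop = FALSE]
  a_mat <- actual$matrix[!act_ctrl, , drop = FALSE]
  idx <- match(a_rec$sample_id, pred$records$sample_id)
  keep <- !is.na(idx)
  if (!all(keep))
    warning(sprintf("%d actual samples without predictions were skipped",
                    sum(!keep)))
  a_rec <- a_rec[keep, , drop = FALSE]
  a_mat <- a_mat[keep, , drop = FALSE]
  p_mat <- pred$matrix[idx[keep], , drop = FALSE]
  ak <- condition_key(a_rec)
  deg_by_cond <- lapply(split(seq_len(nrow(a_mat)), ak), function(rws) {
    am <- colMeans(a_mat[rws, , drop = FALSE])
    select_top_degs(control_mean, am, n_degs, deg_threshold, log_space)
  })
  per_sample <- do.call(rbind, lapply(seq_len(nrow(a_mat)), function(i) {
    degs <- deg_by_cond[[ak[i]]]
    data.frame(sample_id = a_rec$sample_id[i],
               perturbation_id = a_rec$perturbation_id[i],
               context_id = a_rec$context_id[i],
               r2_all = r2_score(p_mat[i, ], a_mat[i, ]),
               ev_all = explained_variance(p_mat[i, ], a_mat[i, ]),
               r2_deg = if (length(degs) >= 2L) r2_score(p_mat[i, degs], a_mat[i, degs]) else NA_real_,
               ev_deg = if (length(degs) >= 2L) explained_variance(p_mat[i, degs], a_mat[i, degs]) else NA_real_)
  }))
  per_condition <- do.call(rbind, lapply(split(per_sample, ak), function(df) {
    data.frame(perturbation_id = df$perturbation_id[1],
               context_id = df$context_id[1],
               r2_all = mean(df$r2_all, na.rm = TRUE),
               ev_all = mean(df$ev_all, na.rm = TRUE),
               r2_deg = mean(df$r2_deg, na.rm = TRUE),
               ev_deg = mean(df$ev_deg, na.rm = TRUE),
               n_cells = nrow(df))
  }))
  rownames(per_condition) <- NULL
  out <- summarize_report(per_condition)
  out$per_sample <- per_sample
  out
}
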