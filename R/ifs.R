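#' Incremental feature selection curve
#'
#' For k = 1..K, trains and LOOCV-evaluates a radial-kernel SVM on the
#' continuous (normalized) expression of the top-k ranked genes, recording
#' the confusion counts and Sn/Sp/ACC/MCC at each k. Discretization is used
#' only upstream, for the MI-based ranking; the classifier sees the
#' continuous values.
#'
#' @param em `expr_matrix` with labels.
#' @param ranking `mrmr_ranking` from [mrmr_rank()].
#' @param params `svm_params`.
#' @param K Largest prefix size to evaluate; default the full ranking
#'   length (itself capped at 300 by [mrmr_rank()]).
#' @return Data frame of class `"ifs_curve"` with columns `k`, `Sn`, `Sp`,
#'   `ACC`, `MCC`, `TP`, `FN`, `FP`, `TN`.
#' @export
ifs_curve <- function(em, ranking, params = svm_params(), K = nrow(ranking)) {
  if (!inherits(em, "expr_matrix")) stop("`em` must be an expr_matrix")
  if (K <= 0L) stop("`K` must be positive")
  if (K > nrow(ranking))
    stop("`K` (", K, ") exceeds the ranking length (", nrow(ranking), ")")
  missing <- setdiff(ranking$gene_id[seq_len(K)], colnames(em$values))
  if (length(missing))
    stop("ranked gene(s) absent from the matrix: ", paste(missing, collapse = ", "))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    feats <- em$values[, ranking$gene_id[seq_len(k)], drop = FALSE]
    pred <- loocv_predict(feats, em$labels, params)
    cm <- confusion(pred, em$labels)
    pm <- metrics(cm)
    rows[[k]] <- data.frame(k = k, Sn = pm$Sn, Sp = pm$Sp, ACC = pm$ACC,
                            MCC = pm$MCC, TP = cm$TP, FN = cm$FN,
                            FP = cm$FP, TN = cm$TN)
  }
  structure(do.call(rbind, rows), class = c("ifs_curve", "data.frame"))
}

#' Pick the MCC-maximizing signature from an IFS curve
#'
#' Returns the smallest k attaining the maximal MCC (ties favor the more
#' compact signature) together with the corresponding top-k genes and their
#' LOOCV metrics.
#'
#' @param curve `ifs_curve`.
#' @param ranking The `mrmr_ranking` the curve was computed from.
#' @return List of class `"optimal_signature"`: `k_opt`, `gene_ids`,
#'   `metrics` (a `performance_metrics`), `confusion`.
#' @export
select_optimal <- function(curve, ranking) {
  if (nrow(curve) == 0L) stop("empty IFS curve")
  k_opt <- curve$k[which.max(curve$MCC)]   # first index = smallest k
  row <- curve[curve$k == k_opt, ]
  structure(list(
    k_opt = k_opt,
    gene_ids = ranking$gene_id[seq_len(k_opt)],
    metrics = structure(list(Sn = row$Sn, Sp = row$Sp, ACC = row$ACC,
                             MCC = row$MCC), class = "performance_metrics"),
    confusion = structure(list(TP = row$TP, FN = row$FN, FP = row$FP,
                               TN = row$TN), class = "confusion_matrix")),
    class = "optimal_signature")
}

#' @export
print.optimal_signature <- function(x, ...) {
  cat(sprintf("optimal signature: %d genes, LOOCV MCC = %.3f\n",
              x$k_opt, x$metrics$MCC))
  cat("genes:", paste(x$gene_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full signature-discovery pipeline
#'
#' Executes, in order: input loading (files or synthetic generation), probe
#' collapsing (if a probe map is given), quantile normalization, mean+/-SD
#' discretization, mRMR ranking, the IFS/LOOCV sweep, signature selection,
#' and the per-gene class-direction summary — writing every artifact under
#' `out_dir`. Stage timings and counts are reported via [message()].
#'
#' @param config Named list. Either `synthetic` (a [synthetic_spec()]) or
#'   `matrix_path` + `labels_path` (+ optional `probe_map_path`,
#'   `orientation`) must be given. Optional entries: `top_n` (default 300),
#'   `K` (default `min(top_n, #genes)`), `svm` (an [svm_params()]),
#'   `normalize` (default `TRUE`), `out_dir` (default `"."`).
#' @return List of class `"pipeline_result"`: `expr`, `ranking`, `curve`,
#'   `signature`, `direction`, `paths` (+ `truth` for synthetic runs).
#' @export
run_pipeline <- function(config) {
  top_n <- config$top_n %||% 300
  params <- config$svm %||% svm_params()
  out_dir <- config$out_dir %||% "."
  if (!is.null(config$K) && config$K > top_n)
    stop("`K` (", config$K, ") exceeds `top_n` (", top_n, ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  truth <- NULL
  em <- stage("load", {
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic)
      truth <- cohort$truth
      cohort$expr
    } else {
      if (is.null(config$matrix_path) || is.null(config$labels_path))
        stop("config needs `synthetic` or `matrix_path` + `labels_path`")
      pm <- read_expression_table(config$matrix_path,
                                  config$orientation %||% "samples")
      if (!is.null(config$probe_map_path)) {
        map <- utils::read.delim(config$probe_map_path, header = TRUE,
                                 colClasses = "character")
        pm <- collapse_probes(pm, map)
      }
      expression_matrix(pm, read_labels(config$labels_path))
    }
  })
  message(sprintf("cohort: %d samples (%d case / %d control), %d genes",
                  nrow(em$values), sum(em$labels == "case"),
                  sum(em$labels == "control"), ncol(em$values)))

  if (config$normalize %||% TRUE)
    em <- stage("quantile_normalize", quantile_normalize(em))
  dm <- stage("discretize", discretize_matrix(em))
  ranking <- stage("mrmr_rank", mrmr_rank(dm, em$labels, top_n = top_n))
  K <- config$K %||% nrow(ranking)
  curve <- stage("ifs_curve", ifs_curve(em, ranking, params, K = K))
  sig <- stage("select_optimal", select_optimal(curve, ranking))
  dir <- stage("class_direction", class_direction(em, sig$gene_ids))

  paths <- c(ranking = file.path(out_dir, "ranking.tsv"),
             curve = file.path(out_dir, "ifs_curve.tsv"),
             signature = file.path(out_dir, "signature.txt"),
             metrics = file.path(out_dir, "signature_metrics"))
  write_ranking(ranking, paths["ranking"])
  utils::write.table(curve, paths["curve"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(sprintf("optimal signature size: %d", sig$k_opt),
               sprintf("LOOCV Sn = %.3f, Sp = %.3f, ACC = %.3f, MCC = %.3f",
                       sig$metrics$Sn, sig$metrics$Sp, sig$metrics$ACC,
                       sig$metrics$MCC),
               "",
               "gene_id\tdirection",
               sprintf("%s\t%s", dir$gene_id, dir$direction)),
             paths["signature"])
  write_metrics_report(sig$confusion, paths["metrics"])
  if (!is.null(truth))
    write_cohort(list(expr = em, truth = truth), out_dir)

  structure(list(expr = em, truth = truth, ranking = ranking, curve = curve,
                 signature = sig, direction = dir, paths = paths),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
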