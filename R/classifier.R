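#' Radial-kernel SVM parameters
#'
#' Pins the classifier configuration to the defaults of the reference SVM
#' implementation ([e1071::svm()]): C-classification with a radial basis
#' function kernel, cost 1, gamma = 1 / number of features, and per-feature
#' centering/scaling computed from the training data. Reproducibility of
#' "default parameters" requires pinning all of these explicitly.
#'
#' @param cost Positive soft-margin cost C.
#' @param gamma Positive RBF width, or `"auto"` for 1 / number of features
#'   (resolved at training time).
#' @param standardize Center and scale features using training-fold
#'   statistics (the reference implementation's default).
#' @return List of class `"svm_params"`.
#' @export
svm_params <- function(cost = 1, gamma = "auto", standardize = TRUE) {
  if (!is.numeric(cost) || cost <= 0) stop("`cost` must be > 0")
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("`gamma` must be > 0 or \"auto\"")
  structure(list(cost = cost, gamma = gamma, standardize = isTRUE(standardize)),
            class = "svm_params")
}

#' Train a radial-kernel SVM
#'
#' @param features Numeric matrix, samples x features (continuous
#'   expression values of the selected genes).
#' @param labels Factor of per-sample classes with both `"case"` and
#'   `"control"` present.
#' @param params `svm_params` object.
#' @return Fitted [e1071::svm] model; predict held-out samples with
#'   [stats::predict()] on a matrix with the same feature columns.
#' @export
train_svm <- function(features, labels, params = svm_params()) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("need at least one feature")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("training set contains a single class: ", levels(labels))
  gamma <- if (identical(params$gamma, "auto")) 1 / ncol(features) else params$gamma
  e1071::svm(x = features, y = labels, type = "C-classification",
             kernel = "radial", cost = params$cost, gamma = gamma,
             scale = params$standardize)
}

#' Leave-one-out cross-validated predictions
#'
#' For each sample, an SVM is trained on the remaining n - 1 samples
#' (standardization statistics recomputed within each fold) and predicts
#' the held-out sample. Only the classifier is refit per fold; feature
#' choice and any upstream normalization/discretization are taken as given
#' (see the vignette for the bias this design accepts).
#'
#' @inheritParams train_svm
#' @return Factor of n held-out predictions in sample order, with the same
#'   levels as `labels`.
#' @export
loocv_predict <- function(features, labels, params = svm_params()) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 samples for LOOCV")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("class '", names(counts)[which(counts < 2L)[1L]],
         "' has fewer than 2 samples; every fold must retain both classes")
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- train_svm(features[-i, , drop = FALSE], labels[-i], params)
    pred[i] <- as.character(stats::predict(fit, features[i, , drop = FALSE]))
  }
  factor(pred, levels = levels(labels))
}

#' Confusion matrix with cases as the positive class
#'
#' @param predicted,actual Label vectors of equal length over the same
#'   alphabet.
#' @param positive Label of the positive class (default `"case"`).
#' @return List of class `"confusion_matrix"` with counts `TP` (true
#'   cases), `FN`, `FP`, `TN` (true controls).
#' @export
confusion <- function(predicted, actual, positive = "case") {
  if (length(predicted) != length(actual))
    stop("`predicted` and `actual` must have equal length")
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  alphabet <- unique(actual)
  if (!positive %in% alphabet)
    stop("positive class '", positive, "' absent from `actual`")
  unknown <- setdiff(unique(predicted), alphabet)
  if (length(unknown))
    stop("unknown predicted label(s): ", paste(unknown, collapse = ", "))
  is_pos_a <- actual == positive
  is_pos_p <- predicted == positive
  structure(list(TP = sum(is_pos_p & is_pos_a),
                 FN = sum(!is_pos_p & is_pos_a),
                 FP = sum(is_pos_p & !is_pos_a),
                 TN = sum(!is_pos_p & !is_pos_a)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("            actual case  actual control\n")
  cat(sprintf("pred case   %11d  %14d\n", x$TP, x$FP))
  cat(sprintf("pred ctrl   %11d  %14d\n", x$FN, x$TN))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC from a confusion matrix
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/n, and the Matthews
#' correlation coefficient
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero factor in the MCC denominator yields MCC = 0 by convention. Sn
#' (Sp) is `NA` when there are no actual positives (negatives). MCC is the
#' headline statistic for unbalanced cohorts.
#'
#' @param cm `confusion_matrix` (or list with fields TP, FN, FP, TN).
#' @return List of class `"performance_metrics"` with elements `Sn`, `Sp`,
#'   `ACC`, `MCC`.
#' @examples
#' metrics(confusion(rep(c("case", "control"), c(8, 2)),
#'                   rep(c("case", "control"), c(7, 3))))
#' @export
metrics <- function(cm) {
  tp <- cm$TP; fn <- cm$FN; fp <- cm$FP; tn <- cm$TN
  n <- tp + fn + fp + tn
  if (n < 1L) stop("empty confusion matrix")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(Sn = sn, Sp = sp, ACC = acc, MCC = mcc),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("Sn = %.3f  Sp = %.3f  ACC = %.3f  MCC = %.3f\n",
              x$Sn, x$Sp, x$ACC, x$MCC))
  invisible(x)
}

#' Write a confusion matrix + metrics report
#'
#' Emits a machine-readable TSV (`<path>.tsv`) and a human-readable text
#' report (`<path>.txt`) laying out predicted x actual counts with the four
#' summary statistics.
#'
#' @param cm `confusion_matrix`.
#' @param path Path stem (extensions are appended).
#' @export
write_metrics_report <- function(cm, path) {
  pm <- metrics(cm)
  utils::write.table(
    data.frame(TP = cm$TP, FN = cm$FN, FP = cm$FP, TN = cm$TN,
               Sn = pm$Sn, Sp = pm$Sp, ACC = pm$ACC, MCC = pm$MCC),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- c("Confusion matrix (positive class = case)",
           "                 actual case   actual control",
           sprintf("predicted case   %11d   %14d", cm$TP, cm$FP),
           sprintf("predicted ctrl   %11d   %14d", cm$FN, cm$TN),
           "",
           sprintf("Sn = %.3f, Sp = %.3f, ACC = %.3f, MCC = %.3f",
                   pm$Sn, pm$Sp, pm$ACC, pm$MCC))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
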