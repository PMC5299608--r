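#' Univariate gene-selection criteria
#'
#' Criteria a probe must satisfy to enter the classifier in a given
#' cross-validation fold: Welch p-value below `p_threshold` and a linear
#' fold change of at least `fc_threshold` in either direction (FC >=
#' `fc_threshold` or FC <= 1/`fc_threshold`). If no probe qualifies in a
#' fold, the `fallback_k` probes with the smallest p-values are used
#' instead (and the fold is flagged).
#'
#' @param p_threshold Welch p-value cut (default 0.001).
#' @param fc_threshold Linear fold-change cut (default 4).
#' @param fallback_k Number of top probes used when no probe qualifies.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(p_threshold = 0.001, fc_threshold = 4,
                               fallback_k = 4) {
  stopifnot(p_threshold > 0, p_threshold < 1, fc_threshold > 1, fallback_k >= 1)
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 fallback_k = as.integer(fallback_k)),
            class = "selection_criteria")
}

#' Test probes against the selection criteria
#'
#' @param p_value,fold_change Numeric vectors (recycled together).
#' @param criteria A [selection_criteria()].
#' @return Logical vector: passes both the p and the symmetric fold cut.
#' @export
meets_selection_criteria <- function(p_value, fold_change,
                                     criteria = selection_criteria()) {
  p_value < criteria$p_threshold &
    (fold_change >= criteria$fc_threshold |
       fold_change <= 1 / criteria$fc_threshold)
}

#' Select classifier genes on a set of samples
#'
#' Runs the per-probe Welch test and linear fold change for the contrast and
#' returns the probes meeting the selection criteria; falls back to the top
#' `fallback_k` probes by p-value when none qualifies.
#'
#' @inheritParams de_table
#' @param criteria A [selection_criteria()].
#' @return Character vector of probe ids, with attributes `fallback`
#'   (logical) and `stats` (the underlying tibble).
#' @export
select_features <- function(matrix, annotation, contrast,
                            criteria = selection_criteria()) {
  con <- resolve_contrast(matrix, annotation, contrast)
  w <- row_welch(unclass(matrix), con$idx1, con$idx2)
  fc <- w$mean1_linear / w$mean2_linear
  pass <- meets_selection_criteria(w$p_value, fc, criteria)
  fallback <- !any(pass)
  genes <- if (fallback) {
    rownames(matrix)[order(w$p_value)[seq_len(min(criteria$fallback_k,
                                                  nrow(matrix)))]]
  } else {
    rownames(matrix)[pass]
  }
  stats <- tibble::tibble(probe_id = rownames(matrix),
                          mean1 = w$mean1_linear, mean2 = w$mean2_linear,
                          fold_change = fc, p_value = w$p_value,
                          selected = rownames(matrix) %in% genes)
  structure(genes, fallback = fallback, stats = stats)
}

#' Binary confusion matrix
#'
#' @param tp,fn,fp,tn Non-negative counts; "positive" is the first-listed
#'   contrast class.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Standard definitions with the first-listed class as positive:
#' accuracy = (tp+tn)/n, sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' ppv = tp/(tp+fp), npv = tn/(tn+fn). Ratios with a zero denominator are
#' returned as `NA` (not 0).
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector of proportions.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (cm$tp + cm$tn) / total,
    sensitivity = rat(cm$tp, cm$tp + cm$fn),
    specificity = rat(cm$tn, cm$tn + cm$fp),
    ppv = rat(cm$tp, cm$tp + cm$fp),
    npv = rat(cm$tn, cm$tn + cm$fn))
}

#' Leave-one-out cross-validated linear-SVM classification
#'
#' The signature-building procedure: for every sample of the two contrast
#' classes, gene selection is re-run on the remaining samples only (so the
#' held-out sample never influences its own fold's gene set), a linear-kernel
#' SVM is trained on those genes (log2 intensities, standardized on
#' training-fold statistics), and the held-out sample is predicted. The
#' aggregated predictions form the confusion matrix; a final signature is
#' additionally fitted on all samples with the same criteria.
#'
#' @inheritParams select_features
#' @param cost SVM regularization parameter C (default 1).
#' @return A list of class `classifier_report`: `confusion`
#'   ([confusion_matrix()]), `metrics`, `predictions` (tibble: sample_id,
#'   truth, predicted, correct), `per_fold_genes` (named list),
#'   `fallback_folds`, `final_signature` (tibble: p_value, fdr, mean1,
#'   mean2, fold_change, probe_id), `contrast`.
#' @export
loocv_classify <- function(matrix, annotation, contrast,
                           criteria = selection_criteria(), cost = 1) {
  con <- resolve_contrast(matrix, annotation, contrast, min_per_group = 3)
  keep <- sort(c(con$idx1, con$idx2))
  sub <- matrix[, keep, drop = FALSE]
  cls <- setNames(annotation$class, annotation$sample_id)[colnames(sub)]
  ann_sub <- tibble::tibble(sample_id = colnames(sub), class = unname(cls))
  y <- factor(cls, levels = con$labels)

  n <- ncol(sub)
  predicted <- character(n)
  per_fold_genes <- vector("list", n)
  fallback_folds <- logical(n)
  for (i in seq_len(n)) {
    train <- sub[, -i, drop = FALSE]
    y_train <- y[-i]
    if (any(table(y_train) == 0)) {
      stop("class absent in training fold for sample ", colnames(sub)[i],
           call. = FALSE)
    }
    genes <- select_features(train, ann_sub[-i, ], con$labels, criteria)
    per_fold_genes[[i]] <- as.character(genes)
    fallback_folds[i] <- attr(genes, "fallback")
    x_train <- t(unclass(train)[genes, , drop = FALSE])
    fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                      scale = TRUE)
    x_test <- t(unclass(sub)[genes, i, drop = FALSE])
    predicted[i] <- as.character(predict(fit, x_test))
  }
  names(per_fold_genes) <- colnames(sub)

  truth <- as.character(y)
  pos <- con$labels[1]
  cm <- confusion_matrix(
    tp = sum(truth == pos & predicted == pos),
    fn = sum(truth == pos & predicted != pos),
    fp = sum(truth != pos & predicted == pos),
    tn = sum(truth != pos & predicted != pos)
  )

  final_genes <- select_features(sub, ann_sub, con$labels, criteria)
  de <- de_table(sub, ann_sub, con$labels)
  sig <- de[de$probe_id %in% as.character(final_genes),
            c("p_value", "fdr", "mean1", "mean2", "fold_change", "probe_id")]

  structure(list(
    confusion = cm,
    metrics = confusion_metrics(cm),
    predictions = tibble::tibble(sample_id = colnames(sub), truth = truth,
                                 predicted = predicted,
                                 correct = truth == predicted),
    per_fold_genes = per_fold_genes,
    fallback_folds = fallback_folds,
    final_signature = sig,
    contrast = con$labels
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("LOOCV linear-SVM classifier (%s vs %s)\n",
              x$contrast[1], x$contrast[2]))
  cat(sprintf("  %d/%d %s and %d/%d %s correctly classified\n",
              cm$tp, cm$tp + cm$fn, x$contrast[1],
              cm$tn, cm$tn + cm$fp, x$contrast[2]))
  m <- x$metrics
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              100 * m["accuracy"], 100 * m["sensitivity"],
              100 * m["specificity"], 100 * m["ppv"], 100 * m["npv"]))
  cat(sprintf("  final signature: %s\n",
              paste(x$final_signature$probe_id, collapse = ", ")))
  invisible(x)
}
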