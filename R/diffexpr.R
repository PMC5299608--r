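#' Welch two-sample t-test
#'
#' The unequal-variance t-test used for every probe-level comparison:
#' t = (mean(a) − mean(b)) / sqrt(s²a/na + s²b/nb), degrees of freedom by
#' Welch-Satterthwaite, two-sided p from the Student t distribution.
#'
#' @param a,b Numeric vectors (log2 expression values), each of length >= 2.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- var(a); vb <- var(b)
  se2 <- va / length(a) + vb / length(b)
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means; t undefined, p = 1")
      return(list(t_stat = NA_real_, df = NA_real_, p_value = 1))
    }
    warning("zero variance in both groups with unequal means")
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = .Machine$double.xmin))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t_stat = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

# Vectorized Welch test over the rows of a probe x sample matrix; the
# workhorse behind de_table() and per-fold feature selection. Same formula
# as welch_t(), applied row-wise.
row_welch <- function(vals, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- vals[, idx1, drop = FALSE]; x2 <- vals[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  # degenerate rows (zero variance in both groups)
  flat <- se2 == 0
  if (any(flat)) {
    p[flat] <- ifelse(m1[flat] == m2[flat], 1, .Machine$double.xmin)
    t_stat[flat] <- ifelse(m1[flat] == m2[flat], NA_real_,
                           sign(m1 - m2)[flat] * Inf)
    df[flat] <- NA_real_
  }
  list(t_stat = t_stat, df = df, p_value = p,
       mean1_linear = rowMeans(2^x1), mean2_linear = rowMeans(2^x2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after validating the
#' input range).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Linear fold change
#'
#' Ratio of linear-scale group mean intensities, numerator first. Group
#' means must already be on the linear scale (2^log2 values averaged).
#'
#' @param mean1,mean2 Positive linear-scale group means.
#' @return `mean1 / mean2`.
#' @export
fold_change <- function(mean1, mean2) {
  if (any(mean1 <= 0) || any(mean2 <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  mean1 / mean2
}

# Resolve a contrast specification against an annotation table. Accepts
# "label1:label2" or c("label1", "label2"); returns list of column indices.
resolve_contrast <- function(matrix, annotation, contrast, min_per_group = 2) {
  labels <- if (length(contrast) == 1) {
    strsplit(contrast, ":", fixed = TRUE)[[1]]
  } else contrast
  if (length(labels) != 2) stop("contrast must name exactly two classes", call. = FALSE)
  cls <- setNames(annotation$class, annotation$sample_id)
  avail <- unique(annotation$class)
  if (!all(labels %in% avail)) {
    stop("unknown contrast label(s) ",
         paste(setdiff(labels, avail), collapse = ", "),
         "; available: ", paste(avail, collapse = ", "), call. = FALSE)
  }
  ids <- colnames(matrix)
  idx1 <- which(cls[ids] == labels[1])
  idx2 <- which(cls[ids] == labels[2])
  if (length(idx1) < min_per_group || length(idx2) < min_per_group) {
    stop("each contrast class needs at least ", min_per_group, " samples",
         call. = FALSE)
  }
  list(labels = labels, idx1 = idx1, idx2 = idx2)
}

#' Per-probe differential expression table
#'
#' Welch t-test per probe on log2 values, BH-adjusted p-values, and linear
#' fold changes (first contrast class over second, means of 2^x). Rows are
#' sorted by p-value.
#'
#' @param matrix An [expression_matrix()] (filtered).
#' @param annotation Tibble with `sample_id` and `class` columns.
#' @param contrast `"label1:label2"` or a length-2 character vector; the
#'   first label is the fold-change numerator.
#' @param fdr_threshold Significance cut for the `significant` flag
#'   (default 0.05).
#' @return Tibble with `probe_id`, `mean1`, `mean2` (linear scale),
#'   `fold_change`, `t_stat`, `df`, `p_value`, `fdr`, `significant`.
#' @export
de_table <- function(matrix, annotation, contrast, fdr_threshold = 0.05) {
  con <- resolve_contrast(matrix, annotation, contrast)
  w <- row_welch(unclass(matrix), con$idx1, con$idx2)
  out <- tibble::tibble(
    probe_id = rownames(matrix),
    mean1 = w$mean1_linear,
    mean2 = w$mean2_linear,
    fold_change = w$mean1_linear / w$mean2_linear,
    t_stat = w$t_stat,
    df = w$df,
    p_value = w$p_value,
    fdr = bh_fdr(w$p_value)
  )
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p_value), ]
}
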