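#' Probe-filtering parameters
#'
#' Settings for the two pre-processing filters applied to an RMA-summarized
#' matrix before any statistics: removal of array control probe sets
#' (identified by id prefix) and removal of low-variability probe sets. A
#' probe set is kept only if at least `min_fraction` of samples deviate from
#' the per-probe median by at least `fold_threshold` in either direction on
#' the linear scale (defaults: 15% of samples, 1.5-fold).
#'
#' @param min_fraction Minimum fraction of deviating samples, in (0, 1).
#' @param fold_threshold Linear fold deviation from the median, > 1.
#' @param control_prefixes Character vector of probe-id prefixes marking
#'   control probe sets (default `"AFFX"`).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_fraction = 0.15,
                          fold_threshold = 1.5,
                          control_prefixes = "AFFX") {
  stopifnot(min_fraction > 0, min_fraction < 1, fold_threshold > 1)
  structure(list(min_fraction = min_fraction,
                 fold_threshold = fold_threshold,
                 control_prefixes = as.character(control_prefixes)),
            class = "filter_params")
}

#' Remove control probe sets
#'
#' Drops every probe whose id starts with any of the configured control
#' prefixes. Samples are untouched.
#'
#' @param matrix An [expression_matrix()].
#' @param params A [filter_params()].
#' @return The filtered [expression_matrix()].
#' @export
remove_control_probes <- function(matrix, params = filter_params()) {
  if (nrow(matrix) == 0) stop("empty expression matrix", call. = FALSE)
  if (length(params$control_prefixes) == 0) return(matrix)
  is_ctrl <- Reduce(`|`, lapply(params$control_prefixes,
                                function(p) startsWith(rownames(matrix), p)))
  if (all(is_ctrl)) {
    stop("control-probe filter removed every probe", call. = FALSE)
  }
  matrix[!is_ctrl, , drop = FALSE]
}

#' Filter low-variability probe sets
#'
#' For each probe, counts the samples whose expression deviates from the
#' per-probe median by at least `fold_threshold`-fold in either direction
#' (equivalently, |log2(x) − log2(median)| ≥ log2(fold_threshold), since the
#' matrix is on the log2 scale). Probes with fewer than
#' `min_fraction * n_samples` deviating samples are removed; the boundary
#' count exactly equal to `min_fraction * n_samples` is retained. The
#' per-probe counts are attached as attribute `"filter_report"`.
#'
#' @inheritParams remove_control_probes
#' @return Filtered [expression_matrix()] with a `filter_report` attribute
#'   (tibble: `probe_id`, `n_deviating`, `retained`).
#' @export
variability_filter <- function(matrix, params = filter_params()) {
  if (ncol(matrix) < 2) stop("variability filter needs >= 2 samples", call. = FALSE)
  vals <- unclass(matrix)
  if (any(!is.finite(vals))) {
    bad <- rownames(vals)[which(!is.finite(vals), arr.ind = TRUE)[1, 1]]
    stop("non-finite expression value in probe ", bad, call. = FALSE)
  }
  med <- apply(vals, 1, median)
  dev_count <- rowSums(abs(vals - med) >= log2(params$fold_threshold))
  retained <- dev_count >= params$min_fraction * ncol(vals)
  report <- tibble::tibble(probe_id = rownames(vals),
                           n_deviating = as.integer(dev_count),
                           retained = retained)
  if (!any(retained)) {
    stop("variability filter removed every probe", call. = FALSE)
  }
  out <- matrix[retained, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Run both pre-processing filters
#'
#' Convenience wrapper: control-probe removal followed by the
#' low-variability filter.
#'
#' @inheritParams remove_control_probes
#' @return Filtered [expression_matrix()] (with `filter_report` attribute).
#' @export
preprocess_matrix <- function(matrix, params = filter_params()) {
  variability_filter(remove_control_probes(matrix, params), params)
}
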