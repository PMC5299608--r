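#' Default planted gene signature
#'
#' The four-gene RET mutation-class signature used as the generator default,
#' with the linear fold changes (MEN2A-like over MEN2B-like group means) at
#' which each probe set is planted: NTRK3 and GABRR1 up in MEN2B-like
#' tumours, NNAT and PTPRT up in MEN2A-like tumours. Planting these by
#' default means the classifier stage is exercised end-to-end on default
#' simulations.
#'
#' @return A data.frame with columns `probe_id`, `symbol`, `fold_change`,
#'   `contrast` (two labels, numerator first).
#' @export
signature_effects <- function() {
  data.frame(
    probe_id = c("7991186", "8062395", "8128087", "8066347"),
    symbol = c("NTRK3", "NNAT", "GABRR1", "PTPRT"),
    fold_change = c(0.21, 6.54, 0.18, 4.06),
    contrast = "MEN2A-like:MEN2B-like",
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic expression-cohort generator. The default
#' class sizes are those of the mutation-class comparison set (21 MEN2A-like
#' vs 9 MEN2B-like tumours); `set_a_class_sizes()` gives the 60-sample
#' hereditary/sporadic design. The baseline model draws a per-probe log2
#' mean from Normal(`baseline_log2_mean`, `baseline_log2_sd`) and adds
#' i.i.d. Gaussian sample noise with sd `noise_log2_sd`; planted probes
#' additionally shift the first contrast class by log2(fold change), so the
#' ratio of linear-scale class means equals the planted fold change in
#' expectation. Noise defaults are assumptions typical of RMA-summarized
#' arrays, not reported values.
#'
#' @param n_probes Number of probe sets (default 10000).
#' @param class_sizes Named integer vector of samples per class.
#' @param planted_effects data.frame with `probe_id`, `fold_change`,
#'   `contrast` ("label1:label2"), optionally `symbol`. Default:
#'   [signature_effects()]. Use `NULL` or an empty frame for a pure null.
#' @param baseline_log2_mean,baseline_log2_sd Probe-level mean distribution
#'   on the log2 scale.
#' @param noise_log2_sd Within-class per-sample log2 noise sd.
#' @param control_fraction Fraction of probes given an "AFFX-" control id
#'   (default 0.01), so the control-probe filter has work to do.
#' @param seed Integer RNG seed; a fixed seed makes the output bit-identical
#'   across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 10000,
                       class_sizes = c("MEN2A-like" = 21, "MEN2B-like" = 9),
                       planted_effects = signature_effects(),
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 2,
                       noise_log2_sd = 0.5,
                       control_fraction = 0.01,
                       seed = 1L) {
  stopifnot(n_probes >= 1, length(class_sizes) >= 1)
  if (is.null(names(class_sizes)) || any(!nzchar(names(class_sizes)))) {
    stop("class_sizes must be a named vector", call. = FALSE)
  }
  if (any(class_sizes < 1)) stop("class sizes must be positive", call. = FALSE)
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(probe_id = character(), fold_change = numeric(),
                                  contrast = character(), stringsAsFactors = FALSE)
  }
  if (nrow(planted_effects) > 0 && any(planted_effects$fold_change <= 0)) {
    stop("planted fold changes must be > 0", call. = FALSE)
  }
  stopifnot(baseline_log2_sd > 0, noise_log2_sd >= 0,
            control_fraction >= 0, control_fraction < 1)
  structure(list(
    n_probes = as.integer(n_probes),
    class_sizes = class_sizes,
    planted_effects = planted_effects,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd,
    control_fraction = control_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Class sizes of the 60-sample cancer-genetic-background design
#'
#' 22 hereditary and 38 sporadic MTC samples, the composition used for the
#' hereditary-vs-sporadic contrast.
#' @return Named integer vector.
#' @export
set_a_class_sizes <- function() {
  c(hereditary = 22, sporadic = 38)
}

#' Generate a synthetic expression cohort
#'
#' Draws a log2 expression matrix and a matching sample annotation table
#' under the model described in [sim_config()]. Every non-planted probe has
#' identical distribution in all classes (a global null); each planted probe
#' has the first class of its contrast shifted by log2(fold change).
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `annotation` (a tibble with `sample_id`, `class`, `origin`,
#'   `mutation_class`, `family_id`).
#' @export
generate_expression_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$class_sizes)
  labels <- rep(names(config$class_sizes), times = config$class_sizes)
  sample_ids <- sprintf("MTC%03d", seq_len(n))

  n_ctrl <- floor(config$n_probes * config$control_fraction)
  probe_ids <- c(if (n_ctrl > 0) sprintf("AFFX-ctrl-%04d", seq_len(n_ctrl)),
                 sprintf("%07d", 8000000 + seq_len(config$n_probes - n_ctrl)))
  eff <- config$planted_effects
  if (nrow(eff) > 0) {
    # planted probes replace ids in the non-control block so their ids are known
    missing <- setdiff(eff$probe_id, probe_ids)
    if (length(missing) > 0) {
      slots <- seq(n_ctrl + 1, length.out = length(missing))
      if (max(slots) > config$n_probes) {
        stop("planted probe ids exceed probe range", call. = FALSE)
      }
      probe_ids[slots] <- missing
    }
    if (!all(eff$probe_id %in% probe_ids)) {
      stop("planted probe id not in range", call. = FALSE)
    }
  }

  mu <- rnorm(config$n_probes, config$baseline_log2_mean, config$baseline_log2_sd)
  vals <- mu + matrix(rnorm(config$n_probes * n, 0, config$noise_log2_sd),
                      nrow = config$n_probes, ncol = n)
  dimnames(vals) <- list(probe_ids, sample_ids)

  if (nrow(eff) > 0) {
    con <- strsplit(eff$contrast, ":", fixed = TRUE)
    for (i in seq_len(nrow(eff))) {
      up_class <- con[[i]][1]
      if (!up_class %in% labels) {
        stop("planted contrast class '", up_class, "' not among class labels",
             call. = FALSE)
      }
      idx <- labels == up_class
      vals[eff$probe_id[i], idx] <- vals[eff$probe_id[i], idx] +
        log2(eff$fold_change[i])
    }
  }

  list(matrix = expression_matrix(vals),
       annotation = annotate_cohort(sample_ids, labels))
}

# Build the per-sample annotation. The simulated classes drive the signal;
# origin / mutation_class / family_id mirror the cohort bookkeeping of the
# study design: MEN2A-like mutations occur in both hereditary and sporadic
# tumours (16/21 hereditary), MEN2B-like mostly sporadic (7/9 somatic), and
# two hereditary families contribute two samples each. Family membership is
# annotation only; no within-family correlation is simulated.
annotate_cohort <- function(sample_ids, labels) {
  n <- length(sample_ids)
  origin <- rep(NA_character_, n)
  mutation_class <- rep(NA_character_, n)

  if (all(labels %in% c("MEN2A-like", "MEN2B-like"))) {
    mutation_class <- labels
    a <- which(labels == "MEN2A-like")
    b <- which(labels == "MEN2B-like")
    origin[a] <- rep(c("hereditary", "sporadic"),
                     c(ceiling(length(a) * 16 / 21),
                       length(a) - ceiling(length(a) * 16 / 21)))
    origin[b] <- rep(c("hereditary", "sporadic"),
                     c(ceiling(length(b) * 2 / 9),
                       length(b) - ceiling(length(b) * 2 / 9)))
  } else if (all(labels %in% c("hereditary", "sporadic"))) {
    origin <- labels
    h <- which(labels == "hereditary")
    s <- which(labels == "sporadic")
    # hereditary: mostly exon 10/11 carriers; sporadic: somatic MEN2A/MEN2B,
    # RET-negative, and unknown-status samples in study-like proportions
    mutation_class[h] <- c(rep("MEN2A-like", min(16, length(h))),
                           rep("MEN2B-like", min(2, max(0, length(h) - 16))),
                           rep("unknown", max(0, length(h) - 18)))
    ns <- length(s)
    counts <- round(ns * c(5, 7, 7, 15, 4) / 38)
    counts[5] <- ns - sum(counts[1:4])
    mutation_class[s] <- rep(c("MEN2A-like", "MEN2B-like", "unknown",
                               "RET-negative", "unknown"), counts)
  } else {
    origin <- labels
    mutation_class <- rep("unknown", n)
  }

  family_id <- rep(NA_character_, n)
  her <- which(origin == "hereditary")
  if (length(her) >= 4) family_id[her[1:4]] <- c("F1", "F1", "F2", "F2")

  tibble::tibble(sample_id = sample_ids, class = labels, origin = origin,
                 mutation_class = mutation_class, family_id = family_id)
}

#' Write an annotation table as TSV
#' @param annotation Tibble as returned by [generate_expression_set()].
#' @param path File path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                               na.strings = c("NA", "")))
}
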