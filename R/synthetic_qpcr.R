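#' qPCR simulation configuration
#'
#' Parameters for the synthetic RT-qPCR validation set. The default design
#' mirrors the study's validation cohort: 25 independent tumours (16
#' MEN2A-like, 9 MEN2B-like), nine target genes of which NNAT (fold change
#' 3.3) and CDC14B (2.8) carry a real class effect and the rest are null,
#' three stable reference genes (EIF3S10, HADHA, UBE2D2), and an 8-point
#' 10-fold standard dilution series in duplicate per amplicon.
#'
#' The Cq model is the standard-curve model run forward: each gene g has an
#' intercept (Cq at unit input) and slope −1/log10(1 + E) for amplification
#' efficiency E; sample s contributes a global cDNA input factor; the Cq of
#' (s, g) is intercept + slope * log10(quantity) + Gaussian measurement
#' noise. Reference-gene quantities are exactly proportional across samples
#' (only the input factor varies), which is what geNorm stability M = 0
#' describes at zero noise.
#'
#' @param targets Named numeric vector: target genes and the linear fold
#'   change (first contrast class over second) planted for each; 1 = null.
#' @param reference_genes Character vector of at least two stable genes.
#' @param class_sizes Named integer vector of samples per class.
#' @param contrast `"label1:label2"`; planted fold changes multiply label1.
#' @param n_dilutions,n_replicates Standard-curve design (default 8 x 2).
#' @param efficiency Amplification efficiency E (1 = perfect doubling).
#' @param cq_noise_sd Cq measurement noise, cycles.
#' @param sample_input_log2_sd Spread of per-sample cDNA input (log2 scale).
#' @param seed Integer RNG seed.
#' @return A list of class `qpcr_config`.
#' @export
qpcr_config <- function(targets = c(NNAT = 3.3, CDC14B = 2.8, NALCN = 1,
                                    ZC3H12C = 1, HMGA2 = 1, `HLA-DRB5` = 1,
                                    PDGFRL = 1, ZNF658 = 1, HSD17B14 = 1),
                        reference_genes = c("EIF3S10", "HADHA", "UBE2D2"),
                        class_sizes = c("MEN2A-like" = 16, "MEN2B-like" = 9),
                        contrast = "MEN2A-like:MEN2B-like",
                        n_dilutions = 8,
                        n_replicates = 2,
                        efficiency = 1.0,
                        cq_noise_sd = 0.15,
                        sample_input_log2_sd = 0.5,
                        seed = 1L) {
  if (length(reference_genes) < 2) {
    stop("at least 2 reference genes are required (geNorm is undefined otherwise)",
         call. = FALSE)
  }
  stopifnot(length(targets) >= 1, all(targets > 0),
            n_dilutions >= 3, n_replicates >= 1,
            efficiency > 0, cq_noise_sd >= 0, sample_input_log2_sd >= 0)
  if (is.null(names(targets))) stop("targets must be named", call. = FALSE)
  labels <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(labels) != 2 || !all(labels %in% names(class_sizes))) {
    stop("contrast must name two classes present in class_sizes", call. = FALSE)
  }
  structure(list(targets = targets, reference_genes = reference_genes,
                 class_sizes = class_sizes, contrast = contrast,
                 n_dilutions = as.integer(n_dilutions),
                 n_replicates = as.integer(n_replicates),
                 efficiency = efficiency, cq_noise_sd = cq_noise_sd,
                 sample_input_log2_sd = sample_input_log2_sd,
                 seed = as.integer(seed)),
            class = "qpcr_config")
}

#' Generate a synthetic RT-qPCR dataset
#'
#' @param config A [qpcr_config()].
#' @return A list of class `qpcr_dataset` with elements `records` (tibble:
#'   `sample_id`, `gene`, `replicate`, `cq`), `standard_curves` (tibble:
#'   `gene`, `dilution_step`, `quantity`, `replicate`, `cq`),
#'   `reference_genes`, and `annotation` (tibble: `sample_id`, `class`).
#' @export
generate_qpcr_dataset <- function(config) {
  stopifnot(inherits(config, "qpcr_config"))
  set.seed(config$seed)
  slope <- -1 / log10(1 + config$efficiency)
  labels <- rep(names(config$class_sizes), times = config$class_sizes)
  n <- length(labels)
  sample_ids <- sprintf("VAL%03d", seq_len(n))
  up_class <- strsplit(config$contrast, ":", fixed = TRUE)[[1]][1]

  genes <- c(names(config$targets), config$reference_genes)
  intercept <- setNames(rnorm(length(genes), 24, 1.5), genes)
  abundance <- setNames(2^rnorm(length(genes), 0, 1), genes)
  input <- 2^rnorm(n, 0, config$sample_input_log2_sd)  # per-sample cDNA amount

  grid <- expand.grid(sample = seq_len(n), gene = genes,
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fc <- setNames(rep(1, length(genes)), genes)
  fc[names(config$targets)] <- config$targets
  qty <- input[grid$sample] * abundance[grid$gene] *
    ifelse(labels[grid$sample] == up_class, fc[grid$gene], 1)
  cq <- intercept[grid$gene] + slope * log10(qty) +
    rnorm(nrow(grid), 0, config$cq_noise_sd)
  records <- tibble::tibble(sample_id = sample_ids[grid$sample],
                            gene = grid$gene,
                            replicate = grid$replicate,
                            cq = as.numeric(cq))

  sc <- expand.grid(gene = genes, dilution_step = seq_len(config$n_dilutions),
                    replicate = seq_len(config$n_replicates),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sc$quantity <- 10^(-(sc$dilution_step - 1))
  sc$cq <- intercept[sc$gene] + slope * log10(sc$quantity) +
    rnorm(nrow(sc), 0, config$cq_noise_sd)
  standard_curves <- tibble::as_tibble(sc[, c("gene", "dilution_step",
                                              "quantity", "replicate", "cq")])

  structure(list(records = records,
                 standard_curves = standard_curves,
                 reference_genes = config$reference_genes,
                 annotation = tibble::tibble(sample_id = sample_ids,
                                             class = labels)),
            class = "qpcr_dataset")
}

#' Write a qPCR dataset to long-format TSV files
#'
#' Writes `<prefix>_cq.tsv` (sample, gene, replicate, Cq),
#' `<prefix>_standard_curves.tsv` and `<prefix>_annotation.tsv`.
#'
#' @param dataset A `qpcr_dataset`.
#' @param prefix Path prefix.
#' @export
write_qpcr_tsv <- function(dataset, prefix) {
  write.table(dataset$records, paste0(prefix, "_cq.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$standard_curves, paste0(prefix, "_standard_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$annotation, paste0(prefix, "_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
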