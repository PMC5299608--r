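#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(input quantity) over a dilution
#' series. The slope gives the amplification efficiency
#' E = 10^(−1/slope) − 1; perfect doubling per cycle corresponds to slope
#' −1/log10(2) ≈ −3.3219 and E = 1.
#'
#' @param points data.frame with columns `quantity` (> 0) and `cq`;
#'   replicates are individual rows. At least 3 distinct quantities.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("quantity", "cq") %in% names(points)))
  if (any(points$quantity <= 0)) stop("quantities must be positive", call. = FALSE)
  lq <- log10(points$quantity)
  if (length(unique(lq)) < 3) {
    stop("standard curve needs >= 3 distinct concentrations", call. = FALSE)
  }
  fit <- lm(cq ~ lq, data = data.frame(cq = points$cq, lq = lq))
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((points$cq - mean(points$cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n_points = nrow(points)),
            class = "standard_curve")
}

#' Relative quantity from a Cq value
#'
#' Inverts the fitted standard curve: quantity = 10^((cq − intercept)/slope).
#'
#' @param cq Numeric Cq value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Relative input quantity (same units as the dilution series).
#' @export
relative_quantity <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard-curve slope is zero", call. = FALSE)
  10^((cq - curve$intercept) / curve$slope)
}

#' geNorm reference-gene stability and normalization factors
#'
#' For each reference gene j, stability M_j is the mean over the other
#' reference genes k of the standard deviation across samples of the log2
#' ratios q_j/q_k; perfectly proportional genes have M = 0. The per-sample
#' normalization factor is the geometric mean of the reference-gene
#' quantities (defined up to a global scale). Optionally performs the
#' geNorm stepwise exclusion, repeatedly dropping the least stable gene.
#'
#' @param ref_quantities Numeric matrix, samples x reference genes, positive
#'   relative quantities (rownames = sample ids, colnames = genes).
#' @param iterative If `TRUE`, also return the exclusion ranking.
#' @return A list of class `genorm_result`: `stability` (named M values),
#'   `ranking` (genes from least to most stable), `normalization_factor`
#'   (named per-sample), and if `iterative` the `exclusion_order`.
#' @export
genorm_stability <- function(ref_quantities, iterative = FALSE) {
  q <- as.matrix(ref_quantities)
  if (ncol(q) < 2) stop("geNorm needs at least 2 reference genes", call. = FALSE)
  if (nrow(q) < 3) stop("geNorm needs at least 3 samples", call. = FALSE)
  if (any(q <= 0)) stop("reference quantities must be positive", call. = FALSE)
  genes <- colnames(q)
  if (is.null(genes)) genes <- colnames(q) <- paste0("ref", seq_len(ncol(q)))

  m_values <- function(qq) {
    vapply(seq_len(ncol(qq)), function(j) {
      mean(vapply(setdiff(seq_len(ncol(qq)), j), function(k) {
        sd(log2(qq[, j] / qq[, k]))
      }, numeric(1)))
    }, numeric(1))
  }
  M <- setNames(m_values(q), genes)
  nf <- exp(rowMeans(log(q)))

  exclusion <- NULL
  if (iterative) {
    remaining <- q
    exclusion <- character(0)
    while (ncol(remaining) > 2) {
      m <- m_values(remaining)
      worst <- which.max(m)
      exclusion <- c(exclusion, colnames(remaining)[worst])
      remaining <- remaining[, -worst, drop = FALSE]
    }
    exclusion <- c(exclusion, colnames(remaining)[order(-m_values(remaining))])
  }
  structure(list(stability = M,
                 ranking = names(sort(M, decreasing = TRUE)),
                 normalization_factor = setNames(nf, rownames(q)),
                 exclusion_order = exclusion),
            class = "genorm_result")
}

# Average replicate Cq values and convert to relative quantities via the
# per-gene standard curve; returns a samples x genes matrix.
quantify_qpcr <- function(records, curves) {
  agg <- stats::aggregate(cq ~ sample_id + gene, data = records, FUN = mean)
  samples <- unique(records$sample_id)
  genes <- unique(records$gene)
  out <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
  for (g in genes) {
    rows <- agg$gene == g
    out[agg$sample_id[rows], g] <-
      relative_quantity(agg$cq[rows], curves[[g]])
  }
  if (anyNA(out)) stop("missing Cq for some sample/gene pair", call. = FALSE)
  out
}

#' Compare normalized target-gene quantities between classes
#'
#' Each gene's relative quantities are divided by the per-sample
#' normalization factor, then the two classes are compared with a two-sided
#' Mann-Whitney U test (exact null distribution when both groups are small
#' and untied, normal approximation with tie correction otherwise), with
#' Bonferroni adjustment over `n_tests` genes. The fold change is the ratio
#' of the class means of normalized quantities (first contrast class over
#' second).
#'
#' @param target_quantities Numeric matrix, samples x target genes.
#' @param nf Named per-sample normalization factors.
#' @param annotation Tibble with `sample_id`, `class`.
#' @param contrast `"label1:label2"` or length-2 character vector.
#' @param n_tests Bonferroni family size; defaults to the number of genes
#'   tested.
#' @return Tibble: `gene`, `fold_change`, `u_stat`, `p_value`,
#'   `bonferroni_p`, `significant` (bonferroni_p < 0.05).
#' @export
validate_genes <- function(target_quantities, nf, annotation, contrast,
                           n_tests = ncol(target_quantities)) {
  q <- as.matrix(target_quantities)
  labels <- if (length(contrast) == 1) {
    strsplit(contrast, ":", fixed = TRUE)[[1]]
  } else contrast
  cls <- setNames(annotation$class, annotation$sample_id)[rownames(q)]
  g1 <- which(cls == labels[1]); g2 <- which(cls == labels[2])
  if (length(g1) < 3 || length(g2) < 3) {
    stop("each class needs at least 3 samples", call. = FALSE)
  }
  norm <- q / nf[rownames(q)]
  res <- lapply(colnames(q), function(g) {
    a <- norm[g1, g]; b <- norm[g2, g]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = NULL, correct = TRUE))
    tibble::tibble(gene = g,
                   fold_change = mean(a) / mean(b),
                   u_stat = unname(wt$statistic),
                   p_value = wt$p.value,
                   bonferroni_p = min(1, wt$p.value * n_tests))
  })
  out <- do.call(rbind, res)
  out$significant <- out$bonferroni_p < 0.05
  out
}

#' Run the full qPCR validation stage
#'
#' Fits a standard curve per amplicon, converts Cq to relative quantities,
#' computes geNorm stability and normalization factors from the reference
#' genes, and tests every target gene between the two classes.
#'
#' @param dataset A `qpcr_dataset` (see [generate_qpcr_dataset()]).
#' @param contrast `"label1:label2"`; defaults to the two classes present.
#' @param n_tests Bonferroni family size (default: number of target genes).
#' @return List: `curves` (per-gene [fit_standard_curve()]), `genorm`
#'   ([genorm_stability()]), `results` (per-gene tibble from
#'   [validate_genes()]).
#' @export
qpcr_validation <- function(dataset, contrast = NULL, n_tests = NULL) {
  stopifnot(inherits(dataset, "qpcr_dataset"))
  genes <- unique(dataset$records$gene)
  refs <- dataset$reference_genes
  if (length(setdiff(refs, genes)) > 0) {
    stop("reference genes missing from records: ",
         paste(setdiff(refs, genes), collapse = ", "), call. = FALSE)
  }
  targets <- setdiff(genes, refs)
  if (is.null(contrast)) {
    contrast <- paste(unique(dataset$annotation$class)[1:2], collapse = ":")
  }
  if (is.null(n_tests)) n_tests <- length(targets)

  curves <- lapply(split(dataset$standard_curves, dataset$standard_curves$gene),
                   fit_standard_curve)
  quantities <- quantify_qpcr(dataset$records, curves)
  gn <- genorm_stability(quantities[, refs, drop = FALSE])
  results <- validate_genes(quantities[, targets, drop = FALSE],
                            gn$normalization_factor,
                            dataset$annotation, contrast, n_tests)
  list(curves = curves, genorm = gn, results = results)
}
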