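#' Hierarchical clustering of samples
#'
#' Ward minimum-variance agglomeration on Euclidean distances between sample
#' log2 expression profiles, the unsupervised analysis used to ask whether
#' tumour groups (hereditary vs sporadic; mutation classes) separate
#' globally. Uses the `ward.D2` convention: the Lance-Williams update on
#' squared distances with unsquared Euclidean input.
#'
#' @param matrix An [expression_matrix()] (filtered; probes x samples).
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return An [stats::hclust] object over samples.
#' @export
cluster_samples <- function(matrix, method = "ward.D2") {
  if (ncol(matrix) < 3) stop("clustering needs at least 3 samples", call. = FALSE)
  hclust(dist(t(unclass(matrix)), method = "euclidean"), method = method)
}

#' Cut a dendrogram into k clusters
#'
#' @param dend An [stats::hclust] object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector mapping sample id to cluster.
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
    stop("k must be an integer in [1, ", n, "]", call. = FALSE)
  }
  cutree(dend, k = k)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths are derived from the merge heights (via
#' [ape::as.phylo()]); the file is re-parseable with [ape::read.tree()].
#'
#' @param dend An [stats::hclust] object.
#' @param path Output file path.
#' @return The `phylo` object, invisibly.
#' @export
export_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  phy <- ape::as.phylo(dend)
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' Association between cluster cut and class labels
#'
#' Chi-square test of independence between a k-cluster cut and sample class
#' labels; used to report whether unsupervised structure tracks the
#' annotation (on null data it should not).
#'
#' @param dend An [stats::hclust] object over samples.
#' @param classes Character vector of class labels, named by sample id or in
#'   dendrogram label order.
#' @param k Number of clusters (default 2).
#' @return List with the contingency `table` and chi-square `p_value`.
#' @export
cluster_label_association <- function(dend, classes, k = 2) {
  cl <- cut_tree(dend, k)
  if (!is.null(names(classes))) classes <- classes[names(cl)]
  tab <- table(cluster = cl, class = classes)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  list(table = tab, p_value = p)
}
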