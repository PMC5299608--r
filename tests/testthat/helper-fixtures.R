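# Shared fixtures and independent oracles used across the test files.

# small random log2 expression matrix with ids
random_matrix <- function(n_probes, n_samples, seed = 1, sd = 1, mean = 7) {
  set.seed(seed)
  vals <- matrix(rnorm(n_probes * n_samples, mean, sd), n_probes, n_samples,
                 dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                                 sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(vals)
}

two_class_annotation <- function(sample_ids, n1,
                                 labels = c("MEN2A-like", "MEN2B-like")) {
  tibble::tibble(sample_id = sample_ids,
                 class = rep(labels, c(n1, length(sample_ids) - n1)))
}

# Brute-force variability-filter oracle: tests every (probe, sample) pair
# literally on the linear scale.
oracle_variability_filter <- function(matrix, min_fraction = 0.15,
                                      fold_threshold = 1.5) {
  vals <- 2^unclass(matrix)
  keep <- logical(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    med <- median(vals[i, ])
    count <- 0
    for (j in seq_len(ncol(vals))) {
      x <- vals[i, j]
      if (x / med >= fold_threshold || med / x >= fold_threshold) {
        count <- count + 1
      }
    }
    keep[i] <- count >= min_fraction * ncol(vals)
  }
  rownames(vals)[keep]
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# q_(i) = min over j >= i of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  q
}

# Brute-force agglomerative Ward clustering (ward.D2 convention): the
# Lance-Williams update on squared Euclidean distances, returning merge
# heights on the unsquared scale. Independent of stats::hclust.
oracle_ward_heights <- function(x) {
  d2 <- as.matrix(dist(x))^2
  active <- seq_len(nrow(d2))
  sizes <- rep(1, nrow(d2))
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- d2[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    heights <- c(heights, sqrt(d2[a, b]))
    na <- sizes[a]; nb <- sizes[b]
    for (k in setdiff(active, c(a, b))) {
      nk <- sizes[k]
      d2_new <- ((na + nk) * d2[a, k] + (nb + nk) * d2[b, k] -
                   nk * d2[a, b]) / (na + nb + nk)
      d2[a, k] <- d2[k, a] <- d2_new
    }
    sizes[a] <- na + nb
    active <- setdiff(active, b)
  }
  sort(heights)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
oracle_mw_exact_p <- function(a, b) {
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  n1 <- length(a)
  combos <- utils::combn(length(pooled), n1)
  u_obs <- u_of(a, b)
  mu <- n1 * length(b) / 2
  count <- 0
  for (c_i in seq_len(ncol(combos))) {
    x <- pooled[combos[, c_i]]
    y <- pooled[-combos[, c_i]]
    if (abs(u_of(x, y) - mu) >= abs(u_obs - mu) - 1e-9) count <- count + 1
  }
  count / ncol(combos)
}
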