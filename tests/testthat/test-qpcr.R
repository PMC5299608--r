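test_that("standard-curve fits recover slope, efficiency and r-squared", {
  # perfect doubling: Cq rises one cycle per 2-fold dilution
  q <- 2^-(0:7)
  pts <- data.frame(quantity = rep(q, 2),
                    cq = rep(20 - log2(q), 2))
  fit <- fit_standard_curve(pts)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(fit$efficiency, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # closed form: slope -3.6 -> efficiency 10^(1/3.6) - 1
  pts36 <- data.frame(quantity = 10^-(0:7), cq = 20 + 3.6 * (0:7))
  fit36 <- fit_standard_curve(pts36)
  expect_equal(fit36$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-10)
  expect_equal(fit36$efficiency, 0.8957, tolerance = 1e-4)

  set.seed(2)
  noisy <- data.frame(quantity = 10^-(0:7),
                      cq = 20 + 3.3 * (0:7) + rnorm(8, 0, 0.4))
  expect_lt(fit_standard_curve(noisy)$r_squared, 1)

  expect_error(fit_standard_curve(data.frame(quantity = c(1, 1, 1),
                                             cq = c(1, 2, 3))),
               "distinct")
  expect_error(fit_standard_curve(data.frame(quantity = c(0, 1, 2),
                                             cq = 1:3)), "positive")
})

test_that("relative quantity inverts the curve", {
  pts <- data.frame(quantity = 10^-(0:5), cq = 22 + 3.4 * (0:5))
  fit <- fit_standard_curve(pts)
  expect_equal(relative_quantity(fit$intercept, fit), 1, tolerance = 1e-10)
  # one slope-unit of Cq above the intercept is a 10-fold dilution
  expect_equal(relative_quantity(fit$intercept - fit$slope, fit), 0.1,
               tolerance = 1e-10)
  # round trip quantity -> Cq -> quantity
  q <- c(0.004, 0.31, 2.7)
  cq <- fit$intercept + fit$slope * log10(q)
  expect_equal(relative_quantity(cq, fit), q, tolerance = 1e-10)
})

test_that("geNorm stability matches a hand-computed grid and its invariances", {
  # proportional genes have M = 0
  base <- c(1, 2, 4, 8)
  prop <- cbind(g1 = base, g2 = 3 * base)
  rownames(prop) <- paste0("S", 1:4)
  gn <- genorm_stability(prop)
  expect_equal(unname(gn$stability), c(0, 0), tolerance = 1e-12)

  # 3 genes x 4 samples, hand-worked pairwise log2-ratio SDs:
  # q1 = (1,2,4,8), q2 = (1,4,4,16), q3 = (2,2,8,8)
  # sd(log2 q1/q2) = sd(0,-1,0,-1) = sqrt(1/3)
  # sd(log2 q1/q3) = sd(-1,0,-1,0) = sqrt(1/3)
  # sd(log2 q2/q3) = sd(-1,1,-1,1) = sqrt(4/3)
  grid <- cbind(g1 = c(1, 2, 4, 8), g2 = c(1, 4, 4, 16), g3 = c(2, 2, 8, 8))
  rownames(grid) <- paste0("S", 1:4)
  M <- genorm_stability(grid)$stability
  expect_equal(unname(M["g1"]), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(unname(M["g2"]), mean(c(sqrt(1 / 3), sqrt(4 / 3))), tolerance = 1e-12)
  expect_equal(unname(M["g3"]), mean(c(sqrt(1 / 3), sqrt(4 / 3))), tolerance = 1e-12)

  # normalization factor is the per-sample geometric mean of references
  expect_equal(unname(genorm_stability(grid)$normalization_factor),
               unname(apply(grid, 1, function(r) prod(r)^(1 / 3))),
               tolerance = 1e-12)

  # rescaling one sample scales its NF and leaves M unchanged
  scaled <- grid
  scaled[2, ] <- scaled[2, ] * 7
  gs <- genorm_stability(scaled)
  expect_equal(unname(gs$stability), unname(M), tolerance = 1e-12)
  expect_equal(unname(gs$normalization_factor[2]),
               unname(genorm_stability(grid)$normalization_factor[2]) * 7,
               tolerance = 1e-12)
  # NF invariant to reference-gene order
  expect_equal(unname(genorm_stability(grid[, c(3, 1, 2)])$normalization_factor),
               unname(genorm_stability(grid)$normalization_factor),
               tolerance = 1e-12)

  expect_error(genorm_stability(grid[, 1, drop = FALSE]), "2 reference")
  neg <- grid; neg[1, 1] <- -1
  expect_error(genorm_stability(neg), "positive")

  it <- genorm_stability(grid, iterative = TRUE)
  expect_equal(length(it$exclusion_order), 3)
})

test_that("Mann-Whitney validation matches exact enumeration and handles edge cases", {
  ann <- tibble::tibble(sample_id = paste0("S", 1:6),
                        class = rep(c("A", "B"), each = 3))
  nf <- setNames(rep(1, 6), ann$sample_id)

  q <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(ann$sample_id, "g"))
  res <- validate_genes(q, nf, ann, "A:B", n_tests = 1)
  expect_equal(res$u_stat, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_equal(res$p_value, oracle_mw_exact_p(1:3, 4:6))

  same <- matrix(rep(c(5, 6, 7), 2), ncol = 1,
                 dimnames = list(ann$sample_id, "g"))
  res0 <- validate_genes(same, nf, ann, "A:B", n_tests = 1)
  expect_equal(res0$fold_change, 1)
  expect_equal(res0$p_value, 1)

  # exact p agrees with brute-force enumeration for group sizes up to (6,6)
  set.seed(33)
  for (n1 in c(3, 4, 6)) {
    for (n2 in c(3, 5, 6)) {
      a <- rnorm(n1); b <- rnorm(n2, 0.8)
      wt <- wilcox.test(a, b, exact = TRUE)
      expect_equal(wt$p.value, oracle_mw_exact_p(a, b), tolerance = 1e-12,
                   label = sprintf("exact MW p at (%d,%d)", n1, n2))
    }
  }

  # Bonferroni is capped at 1 and never below the raw p
  d <- generate_qpcr_dataset(qpcr_config(seed = 44))
  v <- qpcr_validation(d, "MEN2A-like:MEN2B-like", n_tests = 9)
  expect_true(all(v$results$bonferroni_p >= v$results$p_value))
  expect_true(all(v$results$bonferroni_p <= 1))
})

test_that("planted validation genes reach Bonferroni significance; nulls do not", {
  runs <- lapply(1:5, function(s) {
    d <- generate_qpcr_dataset(qpcr_config(seed = 600 + s))
    qpcr_validation(d, "MEN2A-like:MEN2B-like", n_tests = 9)$results
  })
  planted_sig <- sapply(runs, function(r) {
    all(r$significant[r$gene %in% c("NNAT", "CDC14B")])
  })
  null_sig <- sapply(runs, function(r) {
    sum(r$significant[!r$gene %in% c("NNAT", "CDC14B")])
  })
  expect_gte(sum(planted_sig), 3)   # majority of seeds
  expect_lte(median(null_sig), 0)
})
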