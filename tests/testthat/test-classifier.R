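test_that("selection criteria require both the p and the symmetric fold cut", {
  crit <- selection_criteria()
  # a strong p-value with only 2-fold change is excluded
  expect_false(meets_selection_criteria(0.0005, 2, crit))
  expect_false(meets_selection_criteria(0.0005, 0.3, crit))
  # 4-fold in either direction with p < 0.001 is included
  expect_true(meets_selection_criteria(0.0005, 4, crit))
  expect_true(meets_selection_criteria(0.0005, 0.25, crit))
  # strong fold change with weak p is excluded
  expect_false(meets_selection_criteria(0.01, 10, crit))
  expect_error(selection_criteria(p_threshold = 2), "p_threshold")
})

test_that("planted strong genes are selected; empty selection falls back to top-k", {
  cfg <- sim_config(n_probes = 800, noise_log2_sd = 0.3, seed = 14)
  d <- generate_expression_set(cfg)
  filt <- preprocess_matrix(d$matrix)
  genes <- select_features(filt, d$annotation, "MEN2A-like:MEN2B-like")
  expect_setequal(as.character(genes), signature_effects()$probe_id)
  expect_false(attr(genes, "fallback"))

  null_d <- generate_expression_set(sim_config(n_probes = 400,
                                               planted_effects = NULL,
                                               seed = 15))
  g0 <- select_features(null_d$matrix, null_d$annotation,
                        "MEN2A-like:MEN2B-like")
  expect_true(attr(g0, "fallback"))
  expect_length(as.character(g0), 4)
})

test_that("confusion metrics follow the standard definitions and flag undefined ratios", {
  cm <- confusion_matrix(tp = 20, fn = 1, fp = 2, tn = 7)
  m <- confusion_metrics(cm)
  expect_equal(unname(m["accuracy"]), 27 / 30)
  expect_equal(unname(m["sensitivity"]), 20 / 21)
  expect_equal(unname(m["specificity"]), 7 / 9)
  expect_equal(unname(m["ppv"]), 20 / 22)
  expect_equal(unname(m["npv"]), 7 / 8)

  perfect <- confusion_metrics(confusion_matrix(tp = 12, fn = 0, fp = 0, tn = 0))
  expect_equal(unname(perfect["accuracy"]), 1)
  expect_true(is.na(perfect["specificity"]))  # no negatives: undefined, not 0
  expect_error(confusion_matrix(-1, 0, 0, 2), "non-negative")
})

test_that("LOOCV recovers a planted signature and a separable gene perfectly", {
  d <- generate_expression_set(sim_config(n_probes = 600, seed = 16))
  filt <- preprocess_matrix(d$matrix)
  rep <- loocv_classify(filt, d$annotation, "MEN2A-like:MEN2B-like")
  expect_gte(rep$metrics[["accuracy"]], 0.9)
  expect_equal(sum(rep$confusion$tp, rep$confusion$fn,
                   rep$confusion$fp, rep$confusion$tn), 30)
  # the signature is drawn from the planted genes only; the three genes whose
  # planted fold change clears the 4-fold cut with margin are always in (the
  # fourth is planted at 4.06, a hair above the cut, so its empirical fold
  # change can fall either side)
  expect_true(all(rep$final_signature$probe_id %in% signature_effects()$probe_id))
  expect_true(all(c("8062395", "7991186", "8128087") %in%
                    rep$final_signature$probe_id))

  # single perfectly separable gene -> 100% accuracy
  one <- generate_expression_set(sim_config(
    n_probes = 100,
    planted_effects = data.frame(probe_id = "SEP", fold_change = 64,
                                 contrast = "MEN2A-like:MEN2B-like"),
    noise_log2_sd = 0.2, control_fraction = 0, seed = 18))
  rep1 <- loocv_classify(one$matrix, one$annotation, "MEN2A-like:MEN2B-like")
  expect_equal(rep1$metrics[["accuracy"]], 1)
})

test_that("feature selection is strictly fold-internal", {
  d <- generate_expression_set(sim_config(n_probes = 300, seed = 19))
  rep <- loocv_classify(d$matrix, d$annotation, "MEN2A-like:MEN2B-like")
  # arbitrarily perturb one held-out sample: its fold's gene set is unchanged
  target <- colnames(d$matrix)[5]
  perturbed <- unclass(d$matrix)
  set.seed(1)
  perturbed[, target] <- perturbed[, target] + rnorm(nrow(perturbed), 0, 5)
  rep2 <- loocv_classify(expression_matrix(perturbed), d$annotation,
                         "MEN2A-like:MEN2B-like")
  expect_identical(rep$per_fold_genes[[target]], rep2$per_fold_genes[[target]])
})

test_that("label permutation destroys classifier performance", {
  d <- generate_expression_set(sim_config(n_probes = 400, seed = 20))
  filt <- preprocess_matrix(d$matrix)
  real_acc <- loocv_classify(filt, d$annotation,
                             "MEN2A-like:MEN2B-like")$metrics[["accuracy"]]
  perm_acc <- sapply(1:5, function(s) {
    set.seed(500 + s)
    ann <- d$annotation
    ann$class <- sample(ann$class)
    loocv_classify(filt, ann, "MEN2A-like:MEN2B-like")$metrics[["accuracy"]]
  })
  # permuted labels carry no information: accuracy collapses to at or below
  # the majority-class rate, far under the real signal
  expect_gte(real_acc, 0.9)
  expect_lte(mean(perm_acc), 21 / 30 + 0.05)
  expect_lt(mean(perm_acc), real_acc - 0.2)
})

test_that("classification is deterministic and errors on invalid designs", {
  d <- generate_expression_set(sim_config(n_probes = 200, seed = 22))
  r1 <- loocv_classify(d$matrix, d$annotation, "MEN2A-like:MEN2B-like")
  r2 <- loocv_classify(d$matrix, d$annotation, "MEN2A-like:MEN2B-like")
  expect_identical(r1$predictions, r2$predictions)

  tiny <- d$annotation
  tiny$class[tiny$class == "MEN2B-like"] <- "MEN2A-like"
  tiny$class[1:2] <- "MEN2B-like"
  expect_error(loocv_classify(d$matrix, tiny, "MEN2A-like:MEN2B-like"),
               "at least 3")
})
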