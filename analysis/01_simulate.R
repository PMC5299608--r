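#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohorts.
#
# Three datasets mirror the study design:
#   * mutation set  — 21 MEN2A-like vs 9 MEN2B-like tumours with the
#     four-gene signature planted (NTRK3 0.21x, NNAT 6.54x, GABRR1 0.18x,
#     PTPRT 4.06x; MEN2A-like over MEN2B-like),
#   * background set — 22 hereditary vs 38 sporadic tumours with NO planted
#     effect (the hereditary/sporadic contrast is simulated as null),
#   * qPCR validation set — 25 independent tumours (16 vs 9), nine target
#     genes of which NNAT (3.3x) and CDC14B (2.8x) are real, three stable
#     reference genes, 8-point standard curves in duplicate.

library(mtcret)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 101

mut <- generate_expression_set(sim_config(n_probes = 5000, seed = seed))
write_expression_tsv(mut$matrix, file.path(out, "mutation_set_expression.tsv"))
write_annotation_tsv(mut$annotation, file.path(out, "mutation_set_annotation.tsv"))
cat(sprintf("mutation set: %d probes x %d samples (%s)\n",
            nrow(mut$matrix), ncol(mut$matrix),
            paste(sprintf("%s=%d", names(table(mut$annotation$class)),
                          table(mut$annotation$class)), collapse = ", ")))

bg <- generate_expression_set(sim_config(n_probes = 5000,
                                         class_sizes = set_a_class_sizes(),
                                         planted_effects = NULL,
                                         seed = seed + 1))
write_expression_tsv(bg$matrix, file.path(out, "background_set_expression.tsv"))
write_annotation_tsv(bg$annotation, file.path(out, "background_set_annotation.tsv"))
cat(sprintf("background set: %d probes x %d samples, no planted effects\n",
            nrow(bg$matrix), ncol(bg$matrix)))

qp <- generate_qpcr_dataset(qpcr_config(seed = seed + 2))
write_qpcr_tsv(qp, file.path(out, "validation"))
cat(sprintf("qPCR validation set: %d samples, %d genes (%d reference), %d standard-curve points\n",
            nrow(qp$annotation), length(unique(qp$records$gene)),
            length(qp$reference_genes), nrow(qp$standard_curves)))
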