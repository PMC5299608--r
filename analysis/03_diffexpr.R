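#!/usr/bin/env Rscript
# Step 3: supervised differential expression.
#
# Per-probe Welch t-tests on log2 values with Benjamini-Hochberg FDR and
# linear fold changes, for both contrasts. Expectation under the simulated
# design: the hereditary-vs-sporadic comparison is null (no probe should
# survive FDR < 0.05 beyond chance), while the MEN2A-like vs MEN2B-like
# comparison recovers the planted signature genes.

library(mtcret)

dir.create("results", showWarnings = FALSE)

run_contrast <- function(set, contrast) {
  m <- read_expression_tsv(sprintf("results/data/%s_expression.tsv", set))
  ann <- read_annotation_tsv(sprintf("results/data/%s_annotation.tsv", set))
  filt <- preprocess_matrix(m)
  de <- de_table(filt, ann, contrast)
  out <- sprintf("results/%s_de_table.tsv", set)
  write.table(format(de, digits = 6), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("%s (%s): %d probes tested, %d at FDR < 0.05\n",
              set, contrast, nrow(de), sum(de$significant)))
  sig <- de[de$significant, ]
  if (nrow(sig) > 0) {
    cat(sprintf("  %-8s FC %5.2f  p %.3g  FDR %.3g\n",
                sig$probe_id, sig$fold_change, sig$p_value, sig$fdr), sep = "")
  }
  invisible(de)
}

run_contrast("background_set", "hereditary:sporadic")
run_contrast("mutation_set", "MEN2A-like:MEN2B-like")
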