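#!/usr/bin/env Rscript
# Step 5: RT-qPCR validation of the mutation-class genes.
#
# Per-amplicon standard curves (Cq regressed on log10 input) give slopes and
# amplification efficiencies; Cq values are converted to relative quantities,
# normalized by the geNorm factor (geometric mean of the EIF3S10 / HADHA /
# UBE2D2 reference quantities), and each of the nine target genes is compared
# between MEN2A-like and MEN2B-like samples by a two-sided Mann-Whitney U
# test with Bonferroni correction over the nine tests.

library(mtcret)

dir.create("results", showWarnings = FALSE)

records <- tibble::as_tibble(read.delim("results/data/validation_cq.tsv"))
curves_raw <- tibble::as_tibble(read.delim("results/data/validation_standard_curves.tsv"))
ann <- read_annotation_tsv("results/data/validation_annotation.tsv")
names(records) <- c("sample_id", "gene", "replicate", "cq")
dataset <- structure(list(records = records, standard_curves = curves_raw,
                          reference_genes = c("EIF3S10", "HADHA", "UBE2D2"),
                          annotation = ann),
                     class = "qpcr_dataset")

v <- qpcr_validation(dataset, "MEN2A-like:MEN2B-like", n_tests = 9)

curve_tab <- do.call(rbind, lapply(names(v$curves), function(g) {
  f <- v$curves[[g]]
  data.frame(gene = g, slope = f$slope, efficiency = f$efficiency,
             r_squared = f$r_squared)
}))
write.table(format(curve_tab, digits = 5), "results/qpcr_standard_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("standard curves: slope %.3f to %.3f, efficiency %.1f%% to %.1f%%\n",
            min(curve_tab$slope), max(curve_tab$slope),
            100 * min(curve_tab$efficiency), 100 * max(curve_tab$efficiency)))

gn <- data.frame(gene = names(v$genorm$stability),
                 M = unname(v$genorm$stability))
write.table(format(gn, digits = 4), "results/qpcr_genorm.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("geNorm stability M: %s\n",
            paste(sprintf("%s=%.3f", gn$gene, gn$M), collapse = ", ")))

write.table(format(v$results, digits = 5), "results/qpcr_validation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nper-gene validation (normalized quantities, Bonferroni over 9 tests):\n")
for (i in seq_len(nrow(v$results))) {
  r <- v$results[i, ]
  cat(sprintf("  %-9s FC %5.2f  U %5.1f  p %8.3g  adj p %8.3g %s\n",
              r$gene, r$fold_change, r$u_stat, r$p_value, r$bonferroni_p,
              if (r$significant) "*" else ""))
}
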