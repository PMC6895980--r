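#!/usr/bin/env Rscript
# Stage 3 — expression filtering, normalization and differential expression.
#
# Keeps genes with >= 5 reads in at least half the samples, normalizes by
# median-of-ratios size factors, and calls DEGs by the NB Wald test with
# BH-adjusted p < 0.05 and fold change > 2 or < 0.5.

library(methexpr)

expr <- read_count_matrix("results/data/counts.tsv",
                          "results/data/samples.csv")
expr_f <- filter_low_expression(expr)
cat("genes:", nrow(expr$counts), "->", nrow(expr_f$counts),
    "after the low-expression filter\n")

expr_n <- normalize_expression(expr_f)
cat("size factors:",
    paste(sprintf("%.2f", range(expr_n$size_factors)), collapse = " - "),
    "(range)\n")

degs <- call_degs(expr_n)
write.table(degs, "results/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("DEGs called:", nrow(degs),
    sprintf("(%d up, %d down)\n", sum(degs$direction == "up"),
            sum(degs$direction == "down")))

truth <- read.delim("results/data/truth_genes.tsv")
planted <- truth$gene[truth$is_deg]
cat(sprintf("recovery vs truth: sensitivity %.3f over %d planted DEGs\n",
            mean(planted %in% degs$gene), length(planted)))
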