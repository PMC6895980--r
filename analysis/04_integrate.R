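#!/usr/bin/env Rscript
# Stage 4 — methylation-expression integration.
#
# Correlates every called DMP with its annotated gene's normalized
# expression across the tumor samples (Spearman, p < 0.05 screen),
# stratifies the significant pairs by promoter/body and CpG context,
# contrasts body:promoter ratios between correlation signs, overlaps with
# the DEG set and classifies concordance quadrants.

library(methexpr)

meth <- read_beta_matrix("results/data/beta.tsv", "results/data/samples.csv")
ann <- read_annotation("results/data/annotation.tsv")
meth_f <- filter_probes(meth, ann)
dmps <- read.delim("results/dmps.tsv")
degs <- read.delim("results/degs.tsv")
expr_n <- normalize_expression(filter_low_expression(
  read_count_matrix("results/data/counts.tsv", "results/data/samples.csv")))

corr <- correlate_dmps(dmps, meth_f, expr_n, ann)
write.table(corr, "results/corr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("significant methylation-expression pairs:", nrow(corr), "of",
    attr(corr, "n_tested"), "tested\n")
cat(sprintf("negative: %d (median rho %.3f) | positive: %d\n",
            sum(corr$sign == "negative"),
            median(corr$rho[corr$sign == "negative"]),
            sum(corr$sign == "positive")))

if (all(c("negative", "positive") %in% corr$sign)) {
  rt <- ratio_test(corr)
  cat(sprintf("body:promoter ratio %.2f (negative) vs %.2f (positive), chi-square p = %.3g\n",
              rt$ratio_negative, rt$ratio_positive, rt$chi2_p))
}

quad <- overlap_with_degs(corr, dmps, degs)
write.table(quad, "results/quadrants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
summ <- integration_summary(corr, quad)
cat("DMP-DEG pairs:", summ$n_pairs_with_deg, "genes:", summ$n_deg_genes,
    "| concordant pairs:", summ$n_concordant_pairs, "\n")
if (!is.null(summ$quadrant_counts)) print(summ$quadrant_counts)
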