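#!/usr/bin/env Rscript
# Stage 5 — over-representation analysis of the correlated genes.
#
# Builds a synthetic gene-set collection over the expression-filtered
# universe (two sets spiked with correlated genes, the rest random) and runs
# the one-sided hypergeometric test with BH adjustment — the local
# counterpart of a web-based enrichment query.

library(methexpr)

expr_n <- normalize_expression(filter_low_expression(
  read_count_matrix("results/data/counts.tsv", "results/data/samples.csv")))
universe <- rownames(expr_n$counts)
corr <- read.delim("results/corr.tsv")
query <- intersect(unique(corr$gene), universe)
cat("query:", length(query), "genes against a universe of",
    length(universe), "\n")

collection <- synthetic_gene_sets(universe, n_sets = 20, set_size = 50,
                                  enriched_genes = query,
                                  n_enriched_sets = 2, seed = 2)
res <- enrich(query, collection, universe)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("significant sets (BH-adjusted p < 0.05):",
    paste(res$set[res$significant], collapse = ", "), "\n")
print(head(res[, c("set", "n_set", "n_overlap", "expected", "p", "adj_p")]),
      row.names = FALSE)
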