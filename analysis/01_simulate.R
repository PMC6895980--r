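#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study cohort.
#
# Generates the default desk-scale cohort (2000 probes x 2000 genes,
# 32 tumors + 5 normals) with planted DMPs (~5% of probes, 85% of them
# hypermethylated, delta-beta 0.35), planted 4-fold DEGs (~30% of genes) and
# methylation->expression couplings (~11% of DMPs, 70% negative), and writes
# the tab-delimited fixture plus truth tables under results/data/.

library(methexpr)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)
write_fixture(sim, "results/data", force = TRUE)

tp <- sim$truth_probes
cat("cohort:", nrow(sim$meth$beta), "probes x", ncol(sim$meth$beta),
    "samples;", nrow(sim$expr$counts), "genes\n")
cat("planted DMPs:", sum(tp$is_dmp),
    sprintf("(%.1f%% hyper)", 100 * mean(tp$true_direction[tp$is_dmp] == "hyper")),
    "| coupled pairs:", sum(!is.na(tp$coupled_gene)),
    sprintf("(%.0f%% negative)",
            100 * mean(tp$coupling_sign[!is.na(tp$coupling_sign)] == -1)), "\n")
cat("planted DEGs:", sum(sim$truth_genes$is_deg), "\n")
cat("fixture written to results/data/\n")
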