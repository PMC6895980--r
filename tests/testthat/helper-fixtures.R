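# Small in-code fixtures shared across test files.

toy_samples <- function(n_tumor = 2, n_normal = 2) {
  data.frame(
    sample_id = c(sprintf("T%d", seq_len(n_tumor)),
                  sprintf("N%d", seq_len(n_normal))),
    group = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    stringsAsFactors = FALSE
  )
}

toy_meth <- function(beta_rows, samples = NULL) {
  # beta_rows: named list probe -> numeric vector
  m <- do.call(rbind, beta_rows)
  rownames(m) <- names(beta_rows)
  if (is.null(samples)) samples <- toy_samples(ncol(m) / 2, ncol(m) / 2)
  colnames(m) <- samples$sample_id
  meth_set(m, samples)
}

toy_annotation <- function(probe_ids, genes = NULL, regions = NULL,
                           chrom = "chr1", context = "OpenSea",
                           snp = FALSE, multimap = FALSE) {
  n <- length(probe_ids)
  probes <- data.frame(
    probe_id = probe_ids,
    chrom = rep_len(chrom, n),
    pos = seq_len(n) * 1000L,
    cpg_context = rep_len(context, n),
    snp_flag = rep_len(snp, n),
    multimap_flag = rep_len(multimap, n),
    stringsAsFactors = FALSE
  )
  if (is.null(genes)) {
    gm <- data.frame(probe_id = character(0), gene = character(0),
                     region = character(0))
  } else {
    gm <- data.frame(probe_id = probe_ids, gene = genes,
                     region = rep_len(if (is.null(regions)) "Body" else
                       regions, n),
                     stringsAsFactors = FALSE)
  }
  probe_annotation(probes, gm)
}

small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(n_probes = 400, n_genes = 400, seed = seed,
                              ...))
}
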