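# Synthetic paired methylation/expression cohorts with planted ground truth.
#
# The generator emulates the structure of a 450K-style tumor/normal study:
# 32 tumors + 5 normals, ~5% of probes differentially methylated with ~85%
# of those hypermethylated, ~11% of DMPs coupled to the expression of their
# annotated gene (mostly with negative sign), and negative-binomial read
# counts with per-sample depth factors recoverable by median-of-ratios.
#
# Randomness is split into three documented streams seeded from the single
# config seed (annotation: seed, methylation: seed + 1, expression: seed + 2)
# so growing the probe set does not reshuffle the gene draws.

#' Simulation configuration
#'
#' Defaults mirror the observed composition of the motivating cohort: 32
#' tumors vs 5 normals, 85% of planted DMPs hypermethylated, 11% of DMPs
#' coupled to their gene's expression, 70% of couplings negative, a planted
#' beta-scale effect of 0.35, and roughly 30% of genes differentially
#' expressed at 4-fold.
#'
#' @param n_probes,n_genes problem size (desk-scale default 2000 each).
#' @param n_tumor,n_normal group sizes.
#' @param frac_dmp fraction of probes planted as DMPs; 0 gives a null cohort.
#' @param frac_hyper_among_dmp fraction of planted DMPs that are
#'   hypermethylated in tumors.
#' @param frac_coupled_among_dmp fraction of planted DMPs whose annotated
#'   gene's tumor expression tracks the probe's beta value.
#' @param frac_negative_among_coupled fraction of couplings with negative
#'   sign.
#' @param effect_delta_beta beta-scale group-mean shift planted at DMPs.
#' @param coupling_strength standard deviation, on the natural-log scale, of
#'   the tumor expression modulation driven by the standardized tumor beta at
#'   the coupled probe; 0 disables coupling.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   mu + dispersion * mu^2), shared across genes.
#' @param frac_deg fraction of genes planted as differentially expressed.
#' @param deg_fold_change planted fold change for differential genes.
#' @param frac_up_among_deg fraction of planted DEGs that are up in tumors.
#' @param region_mix named probabilities over the six region labels used when
#'   a probe-gene association draws its positional label.
#' @param context_mix named probabilities over the six CpG context labels.
#' @param frac_intergenic fraction of probes with no annotated gene.
#' @param frac_two_genes fraction of gene-annotated probes annotated to two
#'   genes (exercises the manifest's semicolon-list dialect).
#' @param frac_sex,frac_snp,frac_multimap fractions of probes on sex
#'   chromosomes / near SNPs / multi-mapping (removed by probe filtering;
#'   nothing is planted on them).
#' @param beta_precision precision of the per-probe Beta noise (higher =
#'   tighter beta values around the probe mean).
#' @param mean_log_expr,sd_log_expr natural-log mean and sd of gene baseline
#'   expression.
#' @param depth_sd sd of the per-sample log-normal depth factors.
#' @param seed integer seed governing all draws.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_probes = 2000, n_genes = 2000,
                       n_tumor = 32, n_normal = 5,
                       frac_dmp = 0.05, frac_hyper_among_dmp = 0.85,
                       frac_coupled_among_dmp = 0.11,
                       frac_negative_among_coupled = 0.70,
                       effect_delta_beta = 0.35,
                       coupling_strength = 0.8,
                       nb_dispersion = 0.2,
                       frac_deg = 0.30, deg_fold_change = 4,
                       frac_up_among_deg = 0.5,
                       region_mix = c(TSS200 = 0.10, TSS1500 = 0.15,
                                      `5UTR` = 0.10, `1stExon` = 0.05,
                                      Body = 0.50, `3UTR` = 0.10),
                       context_mix = c(Island = 0.15, N_Shore = 0.13,
                                       S_Shore = 0.12, N_Shelf = 0.05,
                                       S_Shelf = 0.05, OpenSea = 0.50),
                       frac_intergenic = 0.10, frac_two_genes = 0.10,
                       frac_sex = 0.03, frac_snp = 0.02,
                       frac_multimap = 0.02,
                       beta_precision = 100,
                       mean_log_expr = log(200), sd_log_expr = 1,
                       depth_sd = 0.25,
                       seed = 1) {
  cfg <- list(n_probes = n_probes, n_genes = n_genes, n_tumor = n_tumor,
              n_normal = n_normal, frac_dmp = frac_dmp,
              frac_hyper_among_dmp = frac_hyper_among_dmp,
              frac_coupled_among_dmp = frac_coupled_among_dmp,
              frac_negative_among_coupled = frac_negative_among_coupled,
              effect_delta_beta = effect_delta_beta,
              coupling_strength = coupling_strength,
              nb_dispersion = nb_dispersion, frac_deg = frac_deg,
              deg_fold_change = deg_fold_change,
              frac_up_among_deg = frac_up_among_deg,
              region_mix = region_mix, context_mix = context_mix,
              frac_intergenic = frac_intergenic,
              frac_two_genes = frac_two_genes,
              frac_sex = frac_sex, frac_snp = frac_snp,
              frac_multimap = frac_multimap,
              beta_precision = beta_precision,
              mean_log_expr = mean_log_expr, sd_log_expr = sd_log_expr,
              depth_sd = depth_sd, seed = seed)
  fracs <- c("frac_dmp", "frac_hyper_among_dmp", "frac_coupled_among_dmp",
             "frac_negative_among_coupled", "frac_deg", "frac_up_among_deg",
             "frac_intergenic", "frac_two_genes", "frac_sex", "frac_snp",
             "frac_multimap")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  if (n_tumor + n_normal < 4) stop("n_tumor + n_normal must be >= 4")
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1)
    stop("coupling_strength must be in [0,1]")
  if (cfg$effect_delta_beta < 0 || cfg$effect_delta_beta > 1)
    stop("effect_delta_beta must be in [0,1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$deg_fold_change <= 1) stop("deg_fold_change must be > 1")
  if (!setequal(names(region_mix), REGION_LEVELS) || any(region_mix < 0))
    stop("region_mix must cover exactly the six region labels")
  if (!setequal(names(context_mix), CONTEXT_LEVELS) || any(context_mix < 0))
    stop("context_mix must cover exactly the six context labels")
  planted <- frac_dmp * n_probes
  if (planted > 0 && planted < 1)
    stop("frac_dmp * n_probes is below 1: nothing to plant ",
         "(use frac_dmp = 0 for an explicit null cohort)")
  structure(cfg, class = "sim_config")
}

sample_sheet_for <- function(n_tumor, n_normal) {
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_tumor)),
                  sprintf("N%02d", seq_len(n_normal))),
    group = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a paired methylation/expression cohort
#'
#' Generates a beta-value matrix, a read-count matrix, a manifest-style probe
#' annotation and a ground-truth table, fully reproducible from the config
#' seed. Null probes draw beta values from a per-probe Beta distribution
#' identical in both groups; planted DMPs add \code{effect_delta_beta} to the
#' tumor values (clipped to [0,1], clipping counted in the truth table).
#' Counts are negative binomial around log-normal gene baselines scaled by
#' per-sample depth factors; planted DEGs multiply the tumor mean by the
#' configured fold change; coupled genes additionally modulate each tumor's
#' log-mean by that tumor's standardized beta at the coupled probe, with the
#' planted sign and magnitude \code{coupling_strength}.
#'
#' @param config \code{\link{sim_config}}.
#' @return list with elements \code{meth} (\code{meth_set}), \code{expr}
#'   (\code{expr_set}), \code{annotation} (\code{probe_annotation}),
#'   \code{truth_probes}, \code{truth_genes} (data.frames) and
#'   \code{depth_factors} (the true per-sample factors).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  samples <- sample_sheet_for(cfg$n_tumor, cfg$n_normal)
  tumor_idx <- which(samples$group == "tumor")
  probe_ids <- sprintf("cg%07d", seq_len(cfg$n_probes))
  gene_ids <- sprintf("GENE%05d", seq_len(cfg$n_genes))

  ## -- stream 1: annotation --------------------------------------------------
  set.seed(cfg$seed)
  n_sex <- round(cfg$frac_sex * cfg$n_probes)
  chrom <- sample(paste0("chr", 1:22), cfg$n_probes, replace = TRUE)
  if (n_sex > 0)
    chrom[seq_len(n_sex)] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
  chrom <- sample(chrom)  # shuffle so sex probes are not a prefix
  snp_flag <- stats::runif(cfg$n_probes) < cfg$frac_snp
  multimap_flag <- stats::runif(cfg$n_probes) < cfg$frac_multimap
  cpg_context <- sample(names(cfg$context_mix), cfg$n_probes, replace = TRUE,
                        prob = cfg$context_mix)
  intergenic <- stats::runif(cfg$n_probes) < cfg$frac_intergenic
  two_genes <- !intergenic & stats::runif(cfg$n_probes) < cfg$frac_two_genes
  n_assoc <- ifelse(intergenic, 0L, ifelse(two_genes, 2L, 1L))
  assoc_probe <- rep(probe_ids, n_assoc)
  assoc_gene <- gene_ids[sample.int(cfg$n_genes, sum(n_assoc), replace = TRUE)]
  assoc_region <- sample(names(cfg$region_mix), sum(n_assoc), replace = TRUE,
                         prob = cfg$region_mix)
  probes <- data.frame(
    probe_id = probe_ids, chrom = chrom,
    pos = sample.int(2e8, cfg$n_probes, replace = TRUE),
    cpg_context = cpg_context, snp_flag = snp_flag,
    multimap_flag = multimap_flag, stringsAsFactors = FALSE
  )
  gene_map <- data.frame(probe_id = assoc_probe, gene = assoc_gene,
                         region = assoc_region, stringsAsFactors = FALSE)
  annotation <- probe_annotation(probes, gene_map)

  ## -- stream 2: methylation -------------------------------------------------
  set.seed(cfg$seed + 1L)
  n_dmp <- round(cfg$frac_dmp * cfg$n_probes)
  clean <- !snp_flag & !multimap_flag & !(chrom %in% c("chrX", "chrY")) &
    n_assoc > 0L
  if (n_dmp > sum(clean))
    stop("not enough clean gene-annotated probes to plant ", n_dmp, " DMPs")
  dmp_idx <- sort(sample(which(clean), n_dmp))
  is_dmp <- seq_len(cfg$n_probes) %in% dmp_idx
  hyper <- rep(NA, cfg$n_probes)
  hyper[dmp_idx] <- stats::runif(n_dmp) < cfg$frac_hyper_among_dmp

  ## per-probe baseline means: bimodal for null probes, headroom-aware for
  ## planted probes so the additive effect rarely clips
  base_mean <- ifelse(stats::runif(cfg$n_probes) < 0.5,
                      stats::rbeta(cfg$n_probes, 2, 8),
                      stats::rbeta(cfg$n_probes, 8, 2))
  if (n_dmp > 0) {
    ## shifted tumor means stay at or below 0.90 (or at or above 0.10), the
    ## practical dynamic range of intensity-ratio betas, so the planted
    ## effect does not saturate the scale
    hy <- dmp_idx[hyper[dmp_idx]]
    ho <- dmp_idx[!hyper[dmp_idx]]
    base_mean[hy] <- stats::runif(length(hy), 0.10,
                                  max(0.90 - cfg$effect_delta_beta, 0.11))
    base_mean[ho] <- stats::runif(length(ho),
                                  min(0.10 + cfg$effect_delta_beta, 0.89),
                                  0.90)
  }
  base_mean <- pmin(pmax(base_mean, 0.02), 0.98)
  phi <- cfg$beta_precision
  n_samp <- nrow(samples)
  beta <- matrix(stats::rbeta(cfg$n_probes * n_samp,
                              rep(base_mean, n_samp) * phi,
                              rep(1 - base_mean, n_samp) * phi),
                 nrow = cfg$n_probes, ncol = n_samp,
                 dimnames = list(probe_ids, samples$sample_id))
  n_clipped <- integer(cfg$n_probes)
  if (n_dmp > 0) {
    effect <- ifelse(hyper[dmp_idx], cfg$effect_delta_beta,
                     -cfg$effect_delta_beta)
    shifted <- beta[dmp_idx, tumor_idx, drop = FALSE] + effect
    clipped <- shifted < 0.002 | shifted > 0.998
    n_clipped[dmp_idx] <- rowSums(clipped)
    beta[dmp_idx, tumor_idx] <- pmin(pmax(shifted, 0.002), 0.998)
  }
  ## intensity-ratio betas are never exactly 0 or 1
  beta <- pmin(pmax(beta, 0.002), 0.998)
  meth <- meth_set(beta, samples)

  ## -- stream 3: expression --------------------------------------------------
  set.seed(cfg$seed + 2L)
  ## coupled probes: a subset of planted DMPs with distinct annotated genes
  first_gene <- gene_map$gene[!duplicated(gene_map$probe_id)]
  names(first_gene) <- gene_map$probe_id[!duplicated(gene_map$probe_id)]
  n_coupled <- round(cfg$frac_coupled_among_dmp * n_dmp)
  coupled_probe <- character(0)
  if (n_coupled > 0) {
    cand <- probe_ids[dmp_idx]
    cand <- cand[!duplicated(first_gene[cand])]
    coupled_probe <- sample(cand, min(n_coupled, length(cand)))
  }
  coupling_sign <- stats::setNames(
    ifelse(stats::runif(length(coupled_probe)) <
             cfg$frac_negative_among_coupled, -1L, 1L),
    coupled_probe)
  coupled_gene <- first_gene[coupled_probe]

  base_log <- stats::rnorm(cfg$n_genes, cfg$mean_log_expr, cfg$sd_log_expr)
  is_deg <- stats::runif(cfg$n_genes) < cfg$frac_deg
  deg_up <- rep(NA, cfg$n_genes)
  deg_up[is_deg] <- stats::runif(sum(is_deg)) < cfg$frac_up_among_deg
  depth <- exp(stats::rnorm(n_samp, 0, cfg$depth_sd))
  depth <- depth / exp(mean(log(depth)))

  log_mu <- matrix(base_log, nrow = cfg$n_genes, ncol = n_samp)
  if (any(is_deg)) {
    shift <- ifelse(deg_up[is_deg], log(cfg$deg_fold_change),
                    -log(cfg$deg_fold_change))
    log_mu[is_deg, tumor_idx] <- log_mu[is_deg, tumor_idx] + shift
  }
  if (length(coupled_probe) > 0 && cfg$coupling_strength > 0) {
    for (k in seq_along(coupled_probe)) {
      b <- beta[coupled_probe[k], tumor_idx]
      if (stats::sd(b) > 0) {
        z <- (b - mean(b)) / stats::sd(b)
        g <- match(coupled_gene[k], gene_ids)
        log_mu[g, tumor_idx] <- log_mu[g, tumor_idx] +
          coupling_sign[k] * cfg$coupling_strength * z
      }
    }
  }
  mu <- sweep(exp(log_mu), 2L, depth, `*`)
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           nrow = cfg$n_genes)
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = cfg$n_genes)
  }
  dimnames(counts) <- list(gene_ids, samples$sample_id)
  expr <- expr_set(counts, samples)

  truth_probes <- data.frame(
    probe_id = probe_ids,
    is_dmp = is_dmp,
    true_direction = ifelse(is_dmp, ifelse(hyper, "hyper", "hypo"),
                            NA_character_),
    coupled_gene = NA_character_,
    coupling_sign = NA_integer_,
    n_clipped = n_clipped,
    stringsAsFactors = FALSE
  )
  if (length(coupled_probe) > 0) {
    m <- match(coupled_probe, probe_ids)
    truth_probes$coupled_gene[m] <- unname(coupled_gene)
    truth_probes$coupling_sign[m] <- unname(coupling_sign)
  }
  truth_genes <- data.frame(
    gene = gene_ids,
    is_deg = is_deg,
    true_direction = ifelse(is_deg, ifelse(deg_up, "up", "down"),
                            NA_character_),
    stringsAsFactors = FALSE
  )
  list(meth = meth, expr = expr, annotation = annotation,
       truth_probes = truth_probes, truth_genes = truth_genes,
       depth_factors = stats::setNames(depth, samples$sample_id))
}

#' Write a simulated dataset to disk
#'
#' Emits the core tab-delimited formats plus the truth tables:
#' \code{beta.tsv}, \code{counts.tsv}, \code{annotation.tsv},
#' \code{samples.csv}, \code{truth_probes.tsv}, \code{truth_genes.tsv}.
#'
#' @param dataset output of \code{\link{simulate_dataset}}.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the output directory.
#' @export
write_fixture <- function(dataset, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !force)
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(dataset$meth, file.path(outdir, "beta.tsv"))
  write_count_matrix(dataset$expr, file.path(outdir, "counts.tsv"))
  write_annotation(dataset$annotation, file.path(outdir, "annotation.tsv"))
  write_sample_sheet(dataset$meth$samples, file.path(outdir, "samples.csv"))
  utils::write.table(dataset$truth_probes,
                     file.path(outdir, "truth_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth_genes,
                     file.path(outdir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Generate a synthetic gene-set collection
#'
#' Random gene sets drawn from a universe, optionally spiking a fraction of
#' the first \code{n_enriched_sets} sets with members of a target list so
#' over-representation tests have planted positives.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of sets.
#' @param set_size genes per set.
#' @param enriched_genes optional target gene list.
#' @param n_enriched_sets how many sets to spike.
#' @param enrich_frac fraction of a spiked set drawn from
#'   \code{enriched_genes}.
#' @param seed integer seed.
#' @return \code{\link{gene_set_collection}}.
#' @export
synthetic_gene_sets <- function(universe, n_sets = 20, set_size = 50,
                                enriched_genes = NULL, n_enriched_sets = 2,
                                enrich_frac = 0.5, seed = 1) {
  set.seed(seed)
  universe <- unique(toupper(universe))
  if (set_size > length(universe)) stop("set_size exceeds universe size")
  sets <- lapply(seq_len(n_sets), function(i) {
    g <- sample(universe, set_size)
    if (!is.null(enriched_genes) && i <= n_enriched_sets) {
      k <- min(round(enrich_frac * set_size), length(enriched_genes))
      g <- unique(c(sample(toupper(enriched_genes), k),
                    sample(universe, set_size - k)))
    }
    g
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  gene_set_collection(sets)
}

#' Simulate a targeted validation panel
#'
#' Emulates the independent validation arm: a handful of CpGs measured by
#' pyrosequencing (percent methylation) and their genes measured by qRT-PCR
#' (relative expression) in a larger tumor cohort, with a planted per-pair
#' coupling between methylation and log expression.
#'
#' @param pairs data.frame with columns \code{cpg_id}, \code{gene}.
#' @param n_tumor validation cohort size (default 83).
#' @param coupling_strength magnitude of the planted coupling (sd of the
#'   log-expression component driven by standardized methylation); 0 for a
#'   null panel.
#' @param coupling_sign +1 or -1, recycled over pairs.
#' @param noise_sd residual sd of log expression.
#' @param seed integer seed.
#' @return list with \code{meth} (samples x CpGs, percent 0-100),
#'   \code{expr} (samples x genes, relative expression), \code{samples}.
#' @export
simulate_validation_panel <- function(pairs, n_tumor = 83,
                                      coupling_strength = 0.8,
                                      coupling_sign = -1,
                                      noise_sd = 0.6, seed = 1) {
  stopifnot(all(c("cpg_id", "gene") %in% names(pairs)))
  set.seed(seed)
  sign_vec <- rep_len(coupling_sign, nrow(pairs))
  sample_ids <- sprintf("V%03d", seq_len(n_tumor))
  genes <- unique(pairs$gene)
  meth <- matrix(NA_real_, n_tumor, nrow(pairs),
                 dimnames = list(sample_ids, pairs$cpg_id))
  expr <- matrix(NA_real_, n_tumor, length(genes),
                 dimnames = list(sample_ids, genes))
  ## one latent methylation state per gene; its CpGs are noisy readouts of it
  ## and expression is coupled to the latent state, so every CpG of a gene
  ## correlates with that gene's expression
  for (g in genes) {
    latent <- stats::rbeta(n_tumor, 0.45 * 12, 0.55 * 12)
    z <- (latent - mean(latent)) / stats::sd(latent)
    rows <- which(pairs$gene == g)
    le <- sign_vec[rows[1L]] * coupling_strength * z +
      stats::rnorm(n_tumor, 0, noise_sd)
    expr[, g] <- 2^le
    for (k in rows) {
      cpg <- pmin(pmax(latent + stats::rnorm(n_tumor, 0, 0.03), 0), 1)
      meth[, k] <- 100 * cpg
    }
  }
  list(meth = meth, expr = expr, samples = sample_ids)
}
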