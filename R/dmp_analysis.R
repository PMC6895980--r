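# Probe filtering and differential methylation between tumor and normal
# groups: Welch t-tests on M-values, effect size thresholded as delta-beta
# (tumor mean minus normal mean on the beta scale), BH-controlled FDR.

#' DMP calling thresholds
#'
#' Defaults: |delta-beta| above 0.2, BH-adjusted p at most 0.005, and (when a
#' detection matrix is present) detection p at most 0.01 in every sample.
#'
#' @param min_abs_delta_beta minimum absolute beta-scale effect, in (0, 1).
#' @param max_adj_p FDR ceiling on the adjusted p-value.
#' @param detection_p_max per-value detection p-value ceiling.
#' @return list of class \code{dmp_thresholds}.
#' @export
dmp_thresholds <- function(min_abs_delta_beta = 0.2, max_adj_p = 0.005,
                           detection_p_max = 0.01) {
  if (min_abs_delta_beta <= 0 || min_abs_delta_beta >= 1)
    stop("min_abs_delta_beta must be in (0,1)")
  if (max_adj_p <= 0 || detection_p_max <= 0)
    stop("thresholds must be positive")
  structure(list(min_abs_delta_beta = min_abs_delta_beta,
                 max_adj_p = max_adj_p,
                 detection_p_max = detection_p_max),
            class = "dmp_thresholds")
}

#' Remove unreliable and sex-chromosome probes
#'
#' Drops probes on chrX/chrY, probes flagged as overlapping SNPs or mapping
#' to multiple locations, and (when a detection matrix is present) probes
#' whose detection p-value exceeds the ceiling in any sample. Probe order is
#' preserved. Every probe in the matrix must be annotated.
#'
#' @param meth \code{\link{meth_set}}.
#' @param annotation \code{\link{probe_annotation}} covering all probes.
#' @param thresholds \code{\link{dmp_thresholds}}.
#' @return filtered \code{meth_set}.
#' @export
filter_probes <- function(meth, annotation, thresholds = dmp_thresholds()) {
  ids <- rownames(meth$beta)
  m <- match(ids, annotation$probes$probe_id)
  if (anyNA(m))
    stop("probe(s) missing from annotation: ",
         paste(ids[is.na(m)], collapse = ", "))
  ann <- annotation$probes[m, ]
  keep <- !(ann$chrom %in% c("chrX", "chrY")) & !ann$snp_flag &
    !ann$multimap_flag
  if (!is.null(meth$detection_p))
    keep <- keep &
      apply(meth$detection_p <= thresholds$detection_p_max, 1L, all)
  meth_set(meth$beta[keep, , drop = FALSE], meth$samples,
           detection_p = if (is.null(meth$detection_p)) NULL else
             meth$detection_p[keep, , drop = FALSE])
}

#' M-values from beta values
#'
#' Logit2 transform \code{M = log2(b / (1 - b))} with beta clipped to
#' \code{[epsilon, 1 - epsilon]} so boundary values stay finite.
#'
#' @param meth \code{meth_set} or a numeric beta matrix/vector.
#' @param epsilon clipping bound.
#' @return matrix (or vector) of M-values.
#' @export
m_values <- function(meth, epsilon = 1e-6) {
  b <- if (inherits(meth, "meth_set")) meth$beta else meth
  b <- pmin(pmax(b, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Per-probe delta-beta
#'
#' Mean beta in tumors minus mean beta in normals, the study's effect-size
#' measure; always in [-1, 1].
#'
#' @param meth \code{\link{meth_set}} with both groups present.
#' @return named numeric vector, one value per probe.
#' @export
delta_beta <- function(meth) {
  idx <- require_two_groups(meth$samples, min_size = 1L)
  rowMeans(meth$beta[, idx$tumor, drop = FALSE]) -
    rowMeans(meth$beta[, idx$normal, drop = FALSE])
}

row_group_stats <- function(m, idx) {
  n <- length(idx)
  x <- m[, idx, drop = FALSE]
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1L)
  list(mean = mu, var = v, n = n)
}

#' Per-probe Welch t-test on M-values
#'
#' Two-sided Welch (unequal variance) t-test comparing tumor and normal
#' M-values for every probe, vectorized over rows. Probes with zero variance
#' in both groups and equal means return p = 1 by convention; zero variance
#' with unequal means returns p = 0.
#'
#' @param meth \code{\link{meth_set}}, at least two samples per group.
#' @param epsilon clipping bound for the M transform.
#' @return data.frame with columns \code{probe_id}, \code{stat}, \code{p}.
#' @export
dmp_test <- function(meth, epsilon = 1e-6) {
  idx <- require_two_groups(meth$samples, min_size = 2L)
  m <- m_values(meth, epsilon)
  g1 <- row_group_stats(m, idx$tumor)
  g0 <- row_group_stats(m, idx$normal)
  se2 <- g1$var / g1$n + g0$var / g0$n
  diff <- g1$mean - g0$mean
  stat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((g1$var / g1$n)^2 / (g1$n - 1L) +
                        (g0$var / g0$n)^2 / (g0$n - 1L)),
               1)
  p <- ifelse(is.finite(stat), 2 * stats::pt(-abs(stat), df),
              0)
  p[se2 == 0 & diff == 0] <- 1
  data.frame(probe_id = rownames(meth$beta), stat = unname(stat),
             p = unname(pmin(p, 1)), stringsAsFactors = FALSE)
}

#' Moderated t-test on M-values
#'
#' Per-probe two-group comparison of M-values with empirical-Bayes variance
#' moderation (limma's linear-model fit and \code{eBayes}), the standard
#' array workhorse and the better-powered choice when one group is small.
#'
#' @inheritParams dmp_test
#' @return data.frame with columns \code{probe_id}, \code{stat}, \code{p}.
#' @export
dmp_test_moderated <- function(meth, epsilon = 1e-6) {
  require_two_groups(meth$samples, min_size = 2L)
  m <- m_values(meth, epsilon)
  design <- stats::model.matrix(
    ~ factor(meth$samples$group, levels = c("normal", "tumor")))
  fit <- limma::eBayes(limma::lmFit(m, design))
  data.frame(probe_id = rownames(meth$beta),
             stat = unname(fit$t[, 2L]),
             p = unname(fit$p.value[, 2L]),
             stringsAsFactors = FALSE)
}

#' Call differentially methylated positions
#'
#' Tests every probe on M-values, BH-adjusts over all tested probes, and
#' emits probes with |delta-beta| above the effect threshold and adjusted p
#' at or below the FDR ceiling. Direction is the sign of delta-beta. The
#' default test is the moderated t (\code{\link{dmp_test_moderated}});
#' \code{method = "welch"} uses the self-contained Welch test
#' (\code{\link{dmp_test}}) instead. By default only probes annotated to at
#' least one gene are reported, matching an analysis restricted to CpGs
#' within or near known genes; set \code{restrict_to_genes = FALSE} to keep
#' intergenic probes.
#'
#' @param meth filtered \code{\link{meth_set}}.
#' @param annotation \code{\link{probe_annotation}}.
#' @param thresholds \code{\link{dmp_thresholds}}.
#' @param restrict_to_genes drop probes with no annotated gene.
#' @param method per-probe test to use.
#' @return data.frame of DMP records: \code{probe_id, delta_beta, stat, p,
#'   adj_p, direction}.
#' @export
call_dmps <- function(meth, annotation, thresholds = dmp_thresholds(),
                      restrict_to_genes = TRUE,
                      method = c("moderated", "welch")) {
  method <- match.arg(method)
  tst <- switch(method,
                moderated = dmp_test_moderated(meth),
                welch = dmp_test(meth))
  db <- delta_beta(meth)
  adj <- bh_adjust(tst$p)
  rec <- data.frame(probe_id = tst$probe_id, delta_beta = unname(db),
                    stat = tst$stat, p = tst$p, adj_p = adj,
                    direction = ifelse(db > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  keep <- abs(rec$delta_beta) > thresholds$min_abs_delta_beta &
    rec$adj_p <= thresholds$max_adj_p
  rec <- rec[keep, , drop = FALSE]
  if (restrict_to_genes && nrow(rec) > 0L)
    rec <- rec[rec$probe_id %in% annotation$gene_map$probe_id, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Composition of a DMP set by direction, region and CpG context
#'
#' Tallies DMP records by methylation direction, by promoter/body region
#' class, and by island/shelf-shore/open-sea context class, with percentages
#' printed to one decimal (round-half-up). A probe contributes one count per
#' annotated (gene, region) pair to the region tally, and exactly once to the
#' direction and context tallies.
#'
#' @param records DMP record data.frame (needs \code{probe_id},
#'   \code{direction}).
#' @param annotation \code{\link{probe_annotation}}.
#' @return list of data.frames \code{direction}, \code{region},
#'   \code{context}, each with columns category, count, pct, plus the same
#'   tallies split by direction in \code{region_by_direction} and
#'   \code{context_by_direction}.
#' @export
composition_report <- function(records, annotation) {
  if (nrow(records) == 0L) stop("no DMP records to summarize")
  tally <- function(cat) {
    tab <- table(cat)
    data.frame(category = names(tab), count = as.integer(tab),
               pct = percent_of(as.integer(tab), length(cat)),
               stringsAsFactors = FALSE)
  }
  dir_tab <- tally(records$direction)

  m <- match(records$probe_id, annotation$probes$probe_id)
  if (anyNA(m))
    stop("DMP record probe(s) missing from annotation: ",
         paste(records$probe_id[is.na(m)], collapse = ", "))
  ctx <- context_class(annotation$probes$cpg_context[m])
  ctx_tab <- tally(ctx)

  gm <- annotation$gene_map[annotation$gene_map$probe_id %in%
                              records$probe_id, , drop = FALSE]
  reg_tab <- if (nrow(gm) > 0L) tally(region_class(gm$region)) else
    data.frame(category = character(0), count = integer(0), pct = numeric(0))

  by_dir <- function(values, probe_ids) {
    dirs <- records$direction[match(probe_ids, records$probe_id)]
    do.call(rbind, lapply(split(seq_along(values), dirs), function(i) {
      t <- tally(values[i])
      t$direction <- dirs[i[1L]]
      t
    }))
  }
  list(direction = dir_tab, region = reg_tab, context = ctx_tab,
       region_by_direction = if (nrow(gm) > 0L)
         by_dir(region_class(gm$region), gm$probe_id) else NULL,
       context_by_direction = by_dir(ctx, records$probe_id))
}
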