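# Count filtering, median-of-ratios normalization, fold change and a
# two-group negative-binomial Wald test with method-of-moments dispersion.

#' DEG calling thresholds
#'
#' Defaults: BH-adjusted p below 0.05 with fold change above 2 (or below
#' 1/2), after keeping genes with at least 5 reads in at least half of the
#' samples.
#'
#' @param max_adj_p FDR ceiling.
#' @param min_fc minimum up-regulation fold change (> 1); down-regulation
#'   uses its reciprocal.
#' @param min_reads read floor for the low-expression filter.
#' @param min_sample_frac fraction of samples that must reach the floor.
#' @return list of class \code{deg_thresholds}.
#' @export
deg_thresholds <- function(max_adj_p = 0.05, min_fc = 2.0, min_reads = 5,
                           min_sample_frac = 0.5) {
  if (min_fc <= 1) stop("min_fc must be > 1")
  if (min_reads < 0) stop("min_reads must be >= 0")
  if (min_sample_frac < 0 || min_sample_frac > 1)
    stop("min_sample_frac must be in [0,1]")
  structure(list(max_adj_p = max_adj_p, min_fc = min_fc,
                 min_reads = min_reads, min_sample_frac = min_sample_frac),
            class = "deg_thresholds")
}

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its raw count reaches \code{min_reads} in at least
#' \code{ceiling(min_sample_frac * n_samples)} samples.
#'
#' @param expr \code{\link{expr_set}} with raw counts.
#' @param thresholds \code{\link{deg_thresholds}}.
#' @return filtered \code{expr_set}.
#' @export
filter_low_expression <- function(expr, thresholds = deg_thresholds()) {
  need <- ceiling(thresholds$min_sample_frac * ncol(expr$counts))
  keep <- rowSums(expr$counts >= thresholds$min_reads) >= need
  expr_set(expr$counts[keep, , drop = FALSE], expr$samples,
           size_factors = expr$size_factors)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with nonzero
#' counts in every sample) of the ratio of that sample's count to the gene's
#' geometric mean across samples; factors are rescaled to geometric mean 1.
#' Columns that are exact scalar multiples of each other recover those
#' multiples up to the common rescaling.
#'
#' @param expr \code{\link{expr_set}}.
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(expr) {
  counts <- expr$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in every sample; cannot normalize")
  logc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(logc)
  sf <- apply(exp(logc - geo), 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Attach size factors to an expression set
#' @param expr \code{\link{expr_set}}.
#' @return \code{expr_set} with \code{size_factors} set.
#' @export
normalize_expression <- function(expr) {
  expr_set(expr$counts, expr$samples,
           size_factors = estimate_size_factors(expr))
}

#' Normalized counts
#' @param expr normalized \code{\link{expr_set}}.
#' @return matrix of counts divided by per-sample size factors.
#' @export
normalized_counts <- function(expr) {
  if (is.null(expr$size_factors))
    stop("expression set has no size factors; run normalize_expression()")
  sweep(expr$counts, 2L, expr$size_factors, `/`)
}

#' Per-gene fold change
#'
#' Ratio of mean counts in tumors vs normals, on normalized counts by
#' default, with a pseudocount added to both group means so genes silent in
#' one group stay finite (two silent groups give FC = 1).
#'
#' @param expr \code{\link{expr_set}} (normalized unless
#'   \code{use_normalized = FALSE}).
#' @param pseudocount added to each group mean.
#' @param use_normalized divide by size factors before averaging.
#' @return named positive numeric vector, one fold change per gene.
#' @export
fold_change <- function(expr, pseudocount = 0.5, use_normalized = TRUE) {
  idx <- require_two_groups(expr$samples, min_size = 1L)
  m <- if (use_normalized) normalized_counts(expr) else expr$counts
  mt <- rowMeans(m[, idx$tumor, drop = FALSE])
  mn <- rowMeans(m[, idx$normal, drop = FALSE])
  (mt + pseudocount) / (mn + pseudocount)
}

#' Per-gene negative-binomial Wald test
#'
#' Two-group test on normalized counts. Per gene, the NB dispersion is
#' estimated by method of moments pooled across both groups (variance
#' mu + alpha * mu^2, floored at 1e-8) and a Wald statistic is formed on the
#' difference of log group means, using the delta-method standard error
#' sqrt((1/mu_t + alpha)/n_t + (1/mu_n + alpha)/n_n). Two-sided p-values use
#' a t reference with n - 2 degrees of freedom, which calibrates better than
#' the normal at these group sizes; genes with zero counts everywhere return
#' p = 1.
#'
#' @param expr filtered, normalized \code{\link{expr_set}}; at least two
#'   samples per group.
#' @param pseudocount stabilizer for log means of sparse genes.
#' @return data.frame with columns \code{gene}, \code{stat}, \code{p},
#'   \code{mean_tumor}, \code{mean_normal}, \code{dispersion}.
#' @export
deg_test <- function(expr, pseudocount = 0.5) {
  idx <- require_two_groups(expr$samples, min_size = 2L)
  m <- normalized_counts(expr)
  g1 <- row_group_stats(m, idx$tumor)
  g0 <- row_group_stats(m, idx$normal)
  n1 <- g1$n; n0 <- g0$n
  pool_mean <- (g1$mean * n1 + g0$mean * n0) / (n1 + n0)
  pool_var <- (g1$var * (n1 - 1L) + g0$var * (n0 - 1L)) / (n1 + n0 - 2L)
  alpha <- pmax((pool_var - pool_mean) / pool_mean^2, 1e-8)
  alpha[pool_mean == 0] <- 1e-8
  log_diff <- log(g1$mean + pseudocount) - log(g0$mean + pseudocount)
  se <- sqrt((1 / pmax(g1$mean, pseudocount) + alpha) / n1 +
             (1 / pmax(g0$mean, pseudocount) + alpha) / n0)
  stat <- log_diff / se
  p <- 2 * stats::pt(-abs(stat), n1 + n0 - 2L)
  zero <- g1$mean == 0 & g0$mean == 0
  stat[zero] <- 0
  p[zero] <- 1
  data.frame(gene = rownames(m), stat = unname(stat), p = unname(p),
             mean_tumor = unname(g1$mean), mean_normal = unname(g0$mean),
             dispersion = unname(alpha), stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' BH-adjusts the NB Wald p-values over all tested genes and emits genes with
#' adjusted p below the FDR ceiling and fold change above \code{min_fc} or
#' below \code{1/min_fc}. Direction is up iff FC > 1.
#'
#' @param expr filtered, normalized \code{\link{expr_set}}.
#' @param thresholds \code{\link{deg_thresholds}}.
#' @param use_normalized compute FC on normalized (default) or raw counts.
#' @return data.frame of DEG records: \code{gene, fold_change, mean_tumor,
#'   mean_normal, p, adj_p, direction}.
#' @export
call_degs <- function(expr, thresholds = deg_thresholds(),
                      use_normalized = TRUE) {
  tst <- deg_test(expr)
  fc <- fold_change(expr, use_normalized = use_normalized)
  adj <- bh_adjust(tst$p)
  rec <- data.frame(gene = tst$gene, fold_change = unname(fc),
                    mean_tumor = tst$mean_tumor,
                    mean_normal = tst$mean_normal,
                    p = tst$p, adj_p = adj,
                    direction = ifelse(fc > 1, "up", "down"),
                    stringsAsFactors = FALSE)
  keep <- rec$adj_p < thresholds$max_adj_p &
    (rec$fold_change > thresholds$min_fc |
       rec$fold_change < 1 / thresholds$min_fc)
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
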