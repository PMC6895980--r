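# The integrative core: per-DMP Spearman correlation between CpG methylation
# and annotated-gene expression across tumor samples, stratification by
# promoter/body and island/shelf-shore/open-sea, body:promoter ratio
# contrast between correlation signs, overlap with DEGs, and concordance
# quadrant classification.

#' Integration parameters
#'
#' @param alpha per-pair significance screen on the (unadjusted) Spearman
#'   p-value.
#' @param cohort samples used for the correlation: tumors only (default,
#'   matching a within-tumor coupling analysis) or all samples.
#' @return list of class \code{integration_params}.
#' @export
integration_params <- function(alpha = 0.05,
                               cohort = c("tumor_only", "all_samples")) {
  cohort <- match.arg(cohort)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  structure(list(alpha = alpha, cohort = cohort,
                 promoter_regions = PROMOTER_REGIONS,
                 body_regions = BODY_REGIONS),
            class = "integration_params")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom,
#' standard at cohort sizes in the tens. Constant input is an error (callers
#' skip and log such pairs); |rho| = 1 returns p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return named vector \code{c(rho =, p =)}.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  c(rho = rho, p = p)
}

## one region label per (probe, gene): the most promoter-proximal
pick_region <- function(gene_map) {
  pr <- factor(gene_map$region, levels = REGION_LEVELS)  # priority order
  o <- order(gene_map$probe_id, gene_map$gene, as.integer(pr))
  gm <- gene_map[o, , drop = FALSE]
  gm[!duplicated(gm[, c("probe_id", "gene")]), , drop = FALSE]
}

#' Correlate DMP methylation with annotated-gene expression
#'
#' For every (DMP, annotated gene) pair whose gene is present in the
#' expression set, computes the Spearman correlation between the probe's beta
#' values and the gene's normalized counts over the cohort samples, and emits
#' pairs passing the \code{alpha} screen. Region class comes from the pair's
#' most promoter-proximal label; context class collapses shores and shelves.
#' Pairs whose gene is absent from the expression matrix, or with constant
#' values, are skipped and counted in the \code{skipped} attribute.
#'
#' @param dmps DMP record data.frame (needs \code{probe_id},
#'   \code{direction}).
#' @param meth \code{\link{meth_set}} containing the DMP probes.
#' @param expr filtered, normalized \code{\link{expr_set}}.
#' @param annotation \code{\link{probe_annotation}}.
#' @param params \code{\link{integration_params}}.
#' @return data.frame of correlation records \code{probe_id, gene, rho, p,
#'   sign, region_class, context_class}, with attributes \code{n_tested} and
#'   \code{skipped}.
#' @export
correlate_dmps <- function(dmps, meth, expr, annotation,
                           params = integration_params()) {
  cohort <- if (params$cohort == "tumor_only")
    meth$samples$sample_id[meth$samples$group == "tumor"]
  else meth$samples$sample_id
  missing_expr <- setdiff(cohort, expr$samples$sample_id)
  if (length(missing_expr) > 0L)
    stop("cohort sample(s) absent from expression set: ",
         paste(missing_expr, collapse = ", "))
  norm <- normalized_counts(expr)
  gm <- pick_region(annotation$gene_map[
    annotation$gene_map$probe_id %in% dmps$probe_id, , drop = FALSE])
  in_expr <- gm$gene %in% rownames(norm)
  skipped_missing <- sum(!in_expr)
  gm <- gm[in_expr, , drop = FALSE]
  ctx <- annotation$probes$cpg_context[
    match(gm$probe_id, annotation$probes$probe_id)]

  n_pairs <- nrow(gm)
  rho <- p <- rep(NA_real_, n_pairs)
  skipped_constant <- 0L
  bmat <- meth$beta[, cohort, drop = FALSE]
  emat <- norm[, cohort, drop = FALSE]
  for (i in seq_len(n_pairs)) {
    x <- bmat[gm$probe_id[i], ]
    y <- emat[gm$gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped_constant <- skipped_constant + 1L
      next
    }
    sp <- spearman(x, y)
    rho[i] <- sp[["rho"]]
    p[i] <- sp[["p"]]
  }
  ok <- !is.na(p)
  rec <- data.frame(
    probe_id = gm$probe_id[ok], gene = gm$gene[ok],
    rho = rho[ok], p = p[ok],
    sign = ifelse(rho[ok] < 0, "negative", "positive"),
    region_class = region_class(gm$region[ok]),
    context_class = context_class(ctx[ok]),
    stringsAsFactors = FALSE
  )
  out <- rec[rec$p < params$alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(ok)
  attr(out, "skipped") <- c(gene_missing = skipped_missing,
                            constant = skipped_constant)
  out
}

#' Body:promoter ratio by correlation sign
#'
#' Contrasts where negatively and positively correlated CpGs sit: the
#' body-to-promoter count ratio per sign, and a 1-df chi-square test (no
#' continuity correction) of the 2x2 sign-by-region table. A zero promoter
#' count gives an infinite ratio; the chi-square is still computed.
#'
#' @param corr_records correlation record data.frame.
#' @return list with \code{ratio_negative}, \code{ratio_positive},
#'   \code{chi2}, \code{chi2_p} and the underlying \code{table}.
#' @export
ratio_test <- function(corr_records) {
  if (!all(c("negative", "positive") %in% corr_records$sign))
    stop("both correlation signs must be present")
  tab <- table(factor(corr_records$sign, c("negative", "positive")),
               factor(corr_records$region_class, c("body", "promoter")))
  ratio <- function(s) {
    b <- tab[s, "body"]; pr <- tab[s, "promoter"]
    if (pr == 0) Inf else b / pr
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(ratio_negative = ratio("negative"),
       ratio_positive = ratio("positive"),
       chi2 = unname(ct$statistic), chi2_p = unname(ct$p.value),
       table = tab)
}

#' Concordance of methylation direction, correlation sign and expression
#' direction
#'
#' The expected expression direction is down for (hyper, negative) and
#' (hypo, positive) pairs, up for (hypo, negative) and (hyper, positive);
#' a pair is concordant iff the observed DEG direction matches. Vectorized;
#' a pure function of the three labels.
#'
#' @param meth_direction "hyper"/"hypo".
#' @param corr_sign "negative"/"positive".
#' @param expr_direction "up"/"down".
#' @return logical vector.
#' @export
classify_quadrant <- function(meth_direction, corr_sign, expr_direction) {
  stopifnot(all(meth_direction %in% c("hyper", "hypo")),
            all(corr_sign %in% c("negative", "positive")),
            all(expr_direction %in% c("up", "down")))
  expected <- ifelse((meth_direction == "hyper") == (corr_sign == "negative"),
                     "down", "up")
  expr_direction == expected
}

#' Overlap correlated DMPs with DEGs
#'
#' Inner-joins the correlation records with the DMP table (on probe) and the
#' DEG table (on gene); each surviving (probe, gene) pair becomes one
#' quadrant record carrying the methylation direction, correlation sign,
#' expression direction and the concordance flag.
#'
#' @param corr_records output of \code{\link{correlate_dmps}}.
#' @param dmps DMP record data.frame.
#' @param degs DEG record data.frame.
#' @return data.frame \code{probe_id, gene, meth_direction, corr_sign,
#'   expr_direction, concordant}.
#' @export
overlap_with_degs <- function(corr_records, dmps, degs) {
  keep <- corr_records$probe_id %in% dmps$probe_id &
    corr_records$gene %in% degs$gene
  cr <- corr_records[keep, , drop = FALSE]
  out <- data.frame(
    probe_id = cr$probe_id, gene = cr$gene,
    meth_direction = dmps$direction[match(cr$probe_id, dmps$probe_id)],
    corr_sign = cr$sign,
    expr_direction = degs$direction[match(cr$gene, degs$gene)],
    stringsAsFactors = FALSE
  )
  out$concordant <- if (nrow(out) > 0L)
    classify_quadrant(out$meth_direction, out$corr_sign, out$expr_direction)
  else logical(0)
  rownames(out) <- NULL
  out
}

#' Integration summary counts
#'
#' Rolls the correlation and quadrant tables up into the headline counts:
#' significant pairs and probes, percent of tested DMPs (one decimal,
#' round-half-up), genes involved, the negative/positive split with median
#' rho per sign, quadrant counts and concordant gene/CpG counts. Enforces
#' the arithmetic identities (signs sum to the total; quadrants sum to the
#' pair count).
#'
#' @param corr_records output of \code{\link{correlate_dmps}}.
#' @param quadrants output of \code{\link{overlap_with_degs}} (optional).
#' @param n_tested number of DMPs tested for correlation (defaults to the
#'   \code{n_tested} attribute of \code{corr_records}).
#' @return list of named counts and percentages.
#' @export
integration_summary <- function(corr_records, quadrants = NULL,
                                n_tested = NULL) {
  if (is.null(n_tested)) n_tested <- attr(corr_records, "n_tested")
  n_sig_pairs <- nrow(corr_records)
  sig_probes <- unique(corr_records$probe_id)
  n_neg <- sum(corr_records$sign == "negative")
  n_pos <- sum(corr_records$sign == "positive")
  stopifnot(n_neg + n_pos == n_sig_pairs)
  med_rho <- function(s) {
    v <- corr_records$rho[corr_records$sign == s]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }
  out <- list(
    n_tested = n_tested,
    n_significant = n_sig_pairs,
    n_significant_probes = length(sig_probes),
    pct_significant = if (!is.null(n_tested) && n_tested > 0)
      percent_of(length(sig_probes), n_tested) else NA_real_,
    n_genes = length(unique(corr_records$gene)),
    n_negative = n_neg,
    n_positive = n_pos,
    median_rho_negative = med_rho("negative"),
    median_rho_positive = med_rho("positive")
  )
  if (!is.null(quadrants)) {
    qtab <- table(factor(quadrants$meth_direction, c("hyper", "hypo")),
                  factor(quadrants$corr_sign, c("negative", "positive")))
    out$n_pairs_with_deg <- nrow(quadrants)
    out$n_deg_genes <- length(unique(quadrants$gene))
    out$quadrant_counts <- qtab
    stopifnot(sum(qtab) == nrow(quadrants))
    out$n_concordant_pairs <- sum(quadrants$concordant)
    out$n_concordant_genes <-
      length(unique(quadrants$gene[quadrants$concordant]))
    out$n_concordant_probes <-
      length(unique(quadrants$probe_id[quadrants$concordant]))
  }
  out
}
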