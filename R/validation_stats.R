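# Statistics for the targeted validation arm: Mann-Whitney group
# comparisons of pyrosequencing methylation, Fisher tests of proportions,
# qPCR relative expression by 2^-dCT, and per-CpG Spearman correlation of a
# small validation panel.

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when \code{n_x * n_y <= 400} and the data are
#' tie-free; normal approximation with tie correction otherwise. Returns the
#' U statistic for \code{x} (number of (x, y) pairs with x > y, ties half).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return named vector \code{c(U =, p =)}.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact,
                       alternative = "two.sided"))
  c(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  stats::fisher.test(tab)$p.value
}

#' Relative expression by the 2^-dCT method
#'
#' \code{2^-(ct_target - ct_reference)}: one cycle earlier than the
#' reference doubles the relative expression.
#'
#' @param ct_target cycle threshold(s) of the target gene.
#' @param ct_reference cycle threshold(s) of the reference gene.
#' @return positive relative expression value(s).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("CT values must be finite")
  2^(-(ct_target - ct_reference))
}

#' Read a percent-methylation table
#'
#' Tab-delimited samples-by-CpGs table of percent methylation (0-100),
#' rescaled to [0, 1] on load.
#'
#' @param path file path; first column sample ids.
#' @return numeric matrix, samples in rows, values in [0, 1].
#' @export
read_percent_meth <- function(path) {
  m <- read_named_matrix(path, what = "percent methylation")
  if (any(m < 0 | m > 100))
    stop("percent methylation outside [0,100] in ", path)
  m / 100
}

#' Per-CpG correlation of a validation panel
#'
#' For each (CpG, gene) pair, the Spearman correlation between the CpG's
#' methylation and the gene's expression over the shared samples — the shape
#' of a targeted validation table. Both tables are indexed by sample (rows).
#' Methylation given on the percent scale (max > 1) is rescaled to [0, 1].
#'
#' @param meth_table samples x CpGs numeric matrix.
#' @param expr_table samples x genes numeric matrix.
#' @param pairs data.frame with columns \code{cpg_id}, \code{gene}.
#' @return data.frame \code{cpg_id, gene, n, rho, p}.
#' @export
validate_cpg_panel <- function(meth_table, expr_table, pairs) {
  stopifnot(all(c("cpg_id", "gene") %in% names(pairs)))
  if (is.null(rownames(meth_table)) || is.null(rownames(expr_table)))
    stop("both tables need sample rownames")
  missing <- setdiff(rownames(meth_table), rownames(expr_table))
  missing2 <- setdiff(rownames(expr_table), rownames(meth_table))
  if (length(missing) > 0L || length(missing2) > 0L)
    stop("sample sets differ between tables; missing: ",
         paste(c(missing, missing2), collapse = ", "))
  bad_cpg <- setdiff(pairs$cpg_id, colnames(meth_table))
  if (length(bad_cpg) > 0L)
    stop("unknown CpG(s) in pairs: ", paste(bad_cpg, collapse = ", "))
  bad_gene <- setdiff(pairs$gene, colnames(expr_table))
  if (length(bad_gene) > 0L)
    stop("unknown gene(s) in pairs: ", paste(bad_gene, collapse = ", "))
  samp <- rownames(meth_table)
  m <- meth_table[samp, , drop = FALSE]
  if (max(m) > 1) m <- m / 100
  e <- expr_table[samp, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    sp <- spearman(m[, pairs$cpg_id[i]], e[, pairs$gene[i]])
    data.frame(cpg_id = pairs$cpg_id[i], gene = pairs$gene[i],
               n = length(samp), rho = sp[["rho"]], p = sp[["p"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
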