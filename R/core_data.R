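# Domain containers and readers/writers for the tab-delimited formats used
# throughout the pipeline: beta-value matrices, count matrices, a probe
# annotation table in the 450K-manifest dialect, sample sheets, and GMT
# gene-set files.

#' Gene-region labels used by the probe annotation
#'
#' The six positional labels a probe-to-gene association may carry, in
#' promoter-proximal priority order (used when one probe maps to one gene
#' under several labels).
#' @export
REGION_LEVELS <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR")

#' CpG-context labels used by the probe annotation
#' @export
CONTEXT_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                    "OpenSea")

#' Region labels collapsed to the promoter class
#' @export
PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon")

#' Region labels collapsed to the gene-body class
#' @export
BODY_REGIONS <- c("Body", "3UTR")

#' Collapse a region label to promoter/body
#'
#' TSS1500, TSS200, 5'UTR and first exon count as promoter; gene body and
#' 3'UTR as body.
#'
#' @param region character vector of region labels.
#' @return character vector, values in \code{c("promoter", "body")}.
#' @export
region_class <- function(region) {
  bad <- setdiff(unique(region), REGION_LEVELS)
  if (length(bad) > 0L)
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  ifelse(region %in% PROMOTER_REGIONS, "promoter", "body")
}

#' Collapse a CpG context label to island/shelf_shore/open_sea
#'
#' @param context character vector of manifest context labels.
#' @return character vector, values in
#'   \code{c("island", "shelf_shore", "open_sea")}.
#' @export
context_class <- function(context) {
  bad <- setdiff(unique(context), CONTEXT_LEVELS)
  if (length(bad) > 0L)
    stop("unknown CpG context label(s): ", paste(bad, collapse = ", "))
  out <- rep("shelf_shore", length(context))
  out[context == "Island"] <- "island"
  out[context == "OpenSea"] <- "open_sea"
  out
}

# ---- sample sheet -----------------------------------------------------------

validate_sample_sheet <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample sheet needs columns sample_id and group")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(samples$group), c("tumor", "normal"))
  if (length(bad) > 0L)
    stop("sample group must be 'tumor' or 'normal', got: ",
         paste(bad, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  samples
}

#' Read a sample sheet
#'
#' CSV with columns \code{sample_id,group}; group is \code{tumor} or
#' \code{normal}.
#'
#' @param path file path.
#' @return data.frame with character columns \code{sample_id}, \code{group}.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(validate_sample_sheet(samples)[, c("sample_id", "group")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- methylation set --------------------------------------------------------

#' Construct a methylation set
#'
#' Bundles a probes-by-samples beta matrix with its sample sheet and an
#' optional detection p-value matrix of the same shape. Beta values must lie
#' in [0, 1] with no missing entries (probes with missing signal are expected
#' to be dropped upstream, not imputed).
#'
#' @param beta numeric matrix, probes in rows, samples in columns.
#' @param samples sample sheet (data.frame with sample_id, group).
#' @param detection_p optional numeric matrix, same dimnames as \code{beta}.
#' @return object of class \code{meth_set} with elements \code{beta},
#'   \code{detection_p}, \code{samples}.
#' @export
meth_set <- function(beta, samples, detection_p = NULL) {
  samples <- validate_sample_sheet(samples)
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe rownames and sample colnames")
  if (anyNA(beta))
    stop("beta contains missing values; probes with missing signal must be removed")
  out_of_range <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(out_of_range) > 0L)
    stop("beta values outside [0,1] for probe(s): ",
         paste(unique(rownames(beta)[out_of_range[, 1L]]), collapse = ", "))
  missing_samples <- setdiff(samples$sample_id, colnames(beta))
  if (length(missing_samples) > 0L)
    stop("sample(s) in sheet but not in beta matrix: ",
         paste(missing_samples, collapse = ", "))
  extra <- setdiff(colnames(beta), samples$sample_id)
  if (length(extra) > 0L)
    stop("sample(s) in beta matrix but not in sheet: ",
         paste(extra, collapse = ", "))
  beta <- beta[, samples$sample_id, drop = FALSE]
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p must have the same shape as beta")
    detection_p <- detection_p[, samples$sample_id, drop = FALSE]
  }
  structure(list(beta = beta, detection_p = detection_p, samples = samples),
            class = "meth_set")
}

#' @export
print.meth_set <- function(x, ...) {
  cat(sprintf("meth_set: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$beta), ncol(x$beta),
              sum(x$samples$group == "tumor"),
              sum(x$samples$group == "normal")))
  invisible(x)
}

read_named_matrix <- function(path, what = "value") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad) > 0L)
      stop(sprintf("non-numeric %s at row '%s', column '%s' in %s",
                   what, ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path))
    stop("non-numeric values in ", path)
  }
  rownames(m) <- ids
  if (anyDuplicated(ids))
    stop("duplicated row ids in ", path)
  m
}

#' Read a beta-value matrix
#'
#' Tab-delimited, first column probe ids, header row of sample ids. Values
#' must be real numbers in [0, 1]; offending probes are reported by name.
#'
#' @param path beta matrix path.
#' @param sample_sheet sample sheet data.frame or path to one.
#' @return \code{\link{meth_set}}.
#' @export
read_beta_matrix <- function(path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  m <- read_named_matrix(path, what = "beta value")
  meth_set(m, sample_sheet)
}

#' Write a beta-value matrix
#' @param meth \code{meth_set}.
#' @param path output path.
#' @export
write_beta_matrix <- function(meth, path) {
  write_matrix_tsv(meth$beta, path, id_col = "probe_id")
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- expression set ---------------------------------------------------------

#' Construct an expression count set
#'
#' Bundles a genes-by-samples matrix of non-negative integer read counts with
#' its sample sheet and optional per-sample size factors.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param samples sample sheet.
#' @param size_factors optional positive numeric vector, one per sample.
#' @return object of class \code{expr_set}.
#' @export
expr_set <- function(counts, samples, size_factors = NULL) {
  samples <- validate_sample_sheet(samples)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers with no missing values")
  missing_samples <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_samples) > 0L)
    stop("sample(s) in sheet but not in count matrix: ",
         paste(missing_samples, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
      stop("size_factors must be positive, one per sample")
    size_factors <- unname(size_factors)
  }
  structure(list(counts = counts, size_factors = size_factors,
                 samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d tumor, %d normal)%s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$group == "tumor"),
              sum(x$samples$group == "normal"),
              if (is.null(x$size_factors)) ", unnormalized" else ", normalized"))
  invisible(x)
}

#' Read a gene-level count matrix
#'
#' Tab-delimited, first column gene symbols, header row of sample ids.
#'
#' @inheritParams read_beta_matrix
#' @return \code{\link{expr_set}} (size factors unset).
#' @export
read_count_matrix <- function(path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  m <- read_named_matrix(path, what = "count")
  expr_set(m, sample_sheet)
}

#' Write a count matrix
#' @param expr \code{expr_set}.
#' @param path output path.
#' @export
write_count_matrix <- function(expr, path) {
  write_matrix_tsv(expr$counts, path, id_col = "gene")
}

# ---- probe annotation -------------------------------------------------------

#' Construct a probe annotation
#'
#' Probe-level table plus an expanded probe-to-gene map. \code{probes} must
#' have columns probe_id, chrom, pos, cpg_context, snp_flag, multimap_flag;
#' \code{gene_map} has one row per (probe_id, gene, region) association.
#' Gene symbols are stored uppercased so that matching against count matrices
#' and gene sets is case-insensitive.
#'
#' @param probes probe-level data.frame.
#' @param gene_map long data.frame with columns probe_id, gene, region.
#' @return object of class \code{probe_annotation}.
#' @export
probe_annotation <- function(probes, gene_map) {
  stopifnot(is.data.frame(probes), is.data.frame(gene_map))
  need <- c("probe_id", "chrom", "pos", "cpg_context", "snp_flag",
            "multimap_flag")
  if (!all(need %in% names(probes)))
    stop("probes table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicated probe_id in annotation")
  bad <- setdiff(unique(probes$cpg_context), CONTEXT_LEVELS)
  if (length(bad) > 0L)
    stop("unknown cpg_context: ", paste(bad, collapse = ", "))
  if (nrow(gene_map) > 0L) {
    bad <- setdiff(unique(gene_map$region), REGION_LEVELS)
    if (length(bad) > 0L)
      stop("unknown region label: ", paste(bad, collapse = ", "))
    orphan <- setdiff(unique(gene_map$probe_id), probes$probe_id)
    if (length(orphan) > 0L)
      stop("gene_map references unknown probe(s): ",
           paste(orphan, collapse = ", "))
    gene_map$gene <- toupper(as.character(gene_map$gene))
    gene_map <- unique(gene_map[, c("probe_id", "gene", "region")])
  }
  probes$probe_id <- as.character(probes$probe_id)
  structure(list(probes = probes, gene_map = gene_map),
            class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes, %d probe-gene associations (%d genes)\n",
              nrow(x$probes), nrow(x$gene_map),
              length(unique(x$gene_map$gene))))
  invisible(x)
}

#' Read a probe annotation table
#'
#' Tab-delimited with columns \code{probe_id, chrom, pos, genes, regions,
#' cpg_context, snp_flag, multimap_flag}. \code{genes} and \code{regions} are
#' semicolon-separated parallel lists (the 450K manifest dialect); an empty
#' gene field marks an intergenic probe. Parallel lists of unequal length are
#' an error naming the probe; duplicate (probe, gene, region) triples are
#' collapsed.
#'
#' @param path annotation TSV path.
#' @return \code{\link{probe_annotation}}.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(genes = "character",
                                            regions = "character"))
  df$genes[is.na(df$genes)] <- ""
  df$regions[is.na(df$regions)] <- ""
  gene_lists <- strsplit(df$genes, ";", fixed = TRUE)
  region_lists <- strsplit(df$regions, ";", fixed = TRUE)
  n_g <- lengths(gene_lists)
  n_r <- lengths(region_lists)
  if (any(n_g != n_r))
    stop("gene/region list length mismatch for probe(s): ",
         paste(df$probe_id[n_g != n_r], collapse = ", "))
  gene_map <- data.frame(
    probe_id = rep(df$probe_id, n_g),
    gene = unlist(gene_lists),
    region = unlist(region_lists),
    stringsAsFactors = FALSE
  )
  probes <- df[, c("probe_id", "chrom", "pos", "cpg_context", "snp_flag",
                   "multimap_flag")]
  probes$snp_flag <- as.logical(probes$snp_flag)
  probes$multimap_flag <- as.logical(probes$multimap_flag)
  probe_annotation(probes, gene_map)
}

#' Write a probe annotation table
#' @param annotation \code{probe_annotation}.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  gm <- annotation$gene_map
  probes <- annotation$probes
  if (nrow(gm) > 0L) {
    genes <- vapply(split(gm$gene, factor(gm$probe_id, probes$probe_id)),
                    paste, "", collapse = ";")
    regions <- vapply(split(gm$region, factor(gm$probe_id, probes$probe_id)),
                      paste, "", collapse = ";")
  } else {
    genes <- regions <- rep("", nrow(probes))
  }
  out <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    pos = probes$pos, genes = genes, regions = regions,
                    cpg_context = probes$cpg_context,
                    snp_flag = probes$snp_flag,
                    multimap_flag = probes$multimap_flag,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GMT gene sets ----------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT: per line, set name, description, then gene symbols, all
#' tab-delimited. Descriptions are discarded; symbols are uppercased;
#' duplicate symbols within a line are stored once. A line with fewer than
#' three fields is an error naming the line; duplicate set names are an
#' error.
#'
#' @param path GMT path.
#' @return named list of character vectors (class \code{gene_set_collection}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nms
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("gene sets must have unique non-empty names")
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection \code{gene_set_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], "na", collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- shared helpers ---------------------------------------------------------

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.05 -> 0.1 at one decimal),
#' matching how the study's percentage tables are printed, unlike base
#' \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scaled <- x * 10^digits
  trunc(abs(scaled) + 0.5 + sqrt(.Machine$double.eps)) * sign(scaled) / 10^digits
}

#' Percentage of a total, one decimal, round-half-up
#' @param count numerator count(s).
#' @param total denominator.
#' @return percentage(s) on the 0-100 scale.
#' @export
percent_of <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  round_half_up(100 * count / total, 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic FDR step-up: with p-values sorted ascending, the adjusted value at
#' rank i is \code{min(p_(j) * n / j)} over j >= i, capped at 1, mapped back
#' to the input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

group_index <- function(samples) {
  list(tumor = which(samples$group == "tumor"),
       normal = which(samples$group == "normal"))
}

require_two_groups <- function(samples, min_size = 1L) {
  idx <- group_index(samples)
  if (length(idx$tumor) < min_size || length(idx$normal) < min_size)
    stop(sprintf("need at least %d sample(s) per group (have %d tumor, %d normal)",
                 min_size, length(idx$tumor), length(idx$normal)))
  idx
}
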