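# Local over-representation analysis: one-sided hypergeometric test per gene
# set against a declared universe, BH-adjusted across sets.

#' Over-representation analysis of a gene list
#'
#' For each set, intersects the set with the universe and computes the
#' hypergeometric upper-tail probability of an overlap at least as large as
#' observed (equivalently a one-sided Fisher test), then BH-adjusts across
#' sets. Sets with adjusted p below \code{alpha} are flagged significant.
#' Gene matching is case-insensitive. The universe should be the set of
#' genes the analysis could have returned (here: genes surviving the
#' expression filter), not the whole genome.
#'
#' @param query_genes character vector of hit genes (must lie within the
#'   universe).
#' @param collection \code{\link{gene_set_collection}}.
#' @param universe character vector of background genes.
#' @param alpha significance ceiling on the adjusted p-value.
#' @return data.frame sorted by p: \code{set, n_set, n_overlap, expected,
#'   p, adj_p, significant, overlap_genes}.
#' @export
enrich <- function(query_genes, collection, universe, alpha = 0.05) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query_genes))
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "),
         if (length(outside) > 5L) ", ..." else "")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_overlap = k,
               expected = n * K / N, p = p,
               overlap_genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  out <- out[order(out$p, out$set), c("set", "n_set", "n_overlap",
                                      "expected", "p", "adj_p",
                                      "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}
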