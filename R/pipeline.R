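# End-to-end orchestration: simulate (or load) -> filter/call DMPs ->
# filter/normalize/call DEGs -> correlate & classify -> enrich, writing every
# intermediate table plus a manifest with row counts and the config hash.

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs)
    stop("config must contain either a 'simulate' block or an 'inputs' block")
  if (has_inputs) {
    need <- c("beta", "counts", "annotation", "samples")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing) > 0L)
      stop("inputs block missing path(s): ", paste(missing, collapse = ", "))
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full integration pipeline
#'
#' Stages: acquire data (simulate from a \code{simulate} config block, or
#' load the four input files named in an \code{inputs} block), filter probes
#' and call DMPs, filter/normalize counts and call DEGs, correlate DMPs with
#' expression, overlap with DEGs and classify concordance quadrants, and
#' (when a GMT is configured) run over-representation analysis of the
#' correlated genes against the expression-filtered universe. Every stage's
#' table is written to \code{out_dir}, along with \code{summary.tsv} and a
#' \code{manifest.json} recording the config hash, seed and per-stage row
#' counts. Re-running with an identical config reproduces identical outputs.
#'
#' @param config list or YAML path. Recognized blocks: \code{simulate}
#'   (fields of \code{\link{sim_config}}) or \code{inputs} (paths
#'   \code{beta, counts, annotation, samples}); optional \code{dmp},
#'   \code{deg}, \code{integration} threshold blocks mirroring
#'   \code{\link{dmp_thresholds}}, \code{\link{deg_thresholds}},
#'   \code{\link{integration_params}}; optional \code{gmt} path.
#' @param out_dir run directory (created; must be empty unless
#'   \code{force}).
#' @param force overwrite an existing non-empty run directory.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  config <- read_pipeline_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("run directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  stage <- "acquire"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, config$simulate)
      sim <- simulate_dataset(cfg)
      write_fixture(sim, file.path(out_dir, "data"), force = force)
      sim
    } else {
      list(meth = read_beta_matrix(config$inputs$beta,
                                   config$inputs$samples),
           expr = read_count_matrix(config$inputs$counts,
                                    config$inputs$samples),
           annotation = read_annotation(config$inputs$annotation),
           truth_probes = NULL, truth_genes = NULL)
    }
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  counts$probes_in <- nrow(result$meth$beta)
  counts$genes_in <- nrow(result$expr$counts)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dmp_thr <- do.call(dmp_thresholds,
                     if (is.null(config$dmp)) list() else config$dmp)
  meth_f <- run_stage("filter_probes",
                      filter_probes(result$meth, result$annotation, dmp_thr))
  dmps <- run_stage("call_dmps",
                    call_dmps(meth_f, result$annotation, dmp_thr))
  counts$probes_filtered <- nrow(meth_f$beta)
  counts$dmps <- write_stage_table(dmps, file.path(out_dir, "dmps.tsv"))

  deg_thr <- do.call(deg_thresholds,
                     if (is.null(config$deg)) list() else config$deg)
  expr_f <- run_stage("filter_low_expression",
                      filter_low_expression(result$expr, deg_thr))
  expr_n <- run_stage("normalize", normalize_expression(expr_f))
  degs <- run_stage("call_degs", call_degs(expr_n, deg_thr))
  counts$genes_filtered <- nrow(expr_n$counts)
  counts$degs <- write_stage_table(degs, file.path(out_dir, "degs.tsv"))

  int_par <- do.call(integration_params,
                     if (is.null(config$integration)) list()
                     else config$integration)
  corr <- run_stage("correlate_dmps",
                    correlate_dmps(dmps, meth_f, expr_n, result$annotation,
                                   int_par))
  counts$correlations <- write_stage_table(corr, file.path(out_dir, "corr.tsv"))
  quadrants <- run_stage("overlap_with_degs",
                         overlap_with_degs(corr, dmps, degs))
  counts$quadrants <- write_stage_table(quadrants,
                                        file.path(out_dir, "quadrants.tsv"))
  summ <- integration_summary(corr, quadrants)
  summ_df <- data.frame(
    quantity = c("n_tested", "n_significant_pairs", "n_significant_probes",
                 "pct_significant", "n_genes", "n_negative", "n_positive",
                 "median_rho_negative", "median_rho_positive",
                 "n_pairs_with_deg", "n_deg_genes", "n_concordant_pairs",
                 "n_concordant_genes"),
    value = c(summ$n_tested, summ$n_significant, summ$n_significant_probes,
              summ$pct_significant, summ$n_genes, summ$n_negative,
              summ$n_positive, summ$median_rho_negative,
              summ$median_rho_positive, summ$n_pairs_with_deg,
              summ$n_deg_genes, summ$n_concordant_pairs,
              summ$n_concordant_genes))
  write_stage_table(summ_df, file.path(out_dir, "summary.tsv"))

  enr <- NULL
  if (!is.null(config$gmt) && nrow(corr) > 0L) {
    collection <- read_gmt(config$gmt)
    universe <- rownames(expr_n$counts)
    query <- intersect(unique(corr$gene), universe)
    enr <- run_stage("enrich", enrich(query, collection, universe))
    counts$enrichment_sets <- write_stage_table(
      enr, file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NULL,
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(meth = meth_f, expr = expr_n, annotation = result$annotation,
                 dmps = dmps, degs = degs, corr = corr,
                 quadrants = quadrants, summary = summ, enrichment = enr,
                 truth_probes = result$truth_probes,
                 truth_genes = result$truth_genes, manifest = manifest))
}
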