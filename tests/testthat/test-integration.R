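# Spearman primitive, DMP-expression correlation, the body:promoter ratio
# contrast, DEG overlap and concordance quadrants.

test_that("spearman: anti-monotone, hand example, and brute-force oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, rev(x))[["rho"]], -1)
  expect_equal(spearman(x, exp(x))[["rho"]], 1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))[["rho"]], 0.6,
               tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- if (rep %% 3 == 0) sample(x) + rpois(n, 2) else rnorm(n)
    sp <- spearman(x, y)
    expect_equal(sp[["rho"]], oracle_spearman_rho(x, y), tolerance = 1e-12)
    # t-approximation p-value from the defining formula
    r <- sp[["rho"]]
    p_ref <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    expect_equal(sp[["p"]], p_ref, tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman(1:3, 3:1), "at least 4")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  transforms <- list(function(v) exp(v), function(v) v^3,
                     function(v) -1 / (1 + exp(-v)), function(v) 5 * v - 2)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    base <- spearman(x, y)[["rho"]]
    f <- transforms[[sample(length(transforms), 1)]]
    increasing <- f(2) > f(1)
    expect_equal(spearman(f(x), y)[["rho"]],
                 if (increasing) base else -base, tolerance = 1e-12)
  }
})

test_that("correlate_dmps recovers planted coupling signs and skips absent genes", {
  sim <- simulate_dataset(sim_config(seed = 1))
  mf <- filter_probes(sim$meth, sim$annotation)
  dmps <- call_dmps(mf, sim$annotation)
  en <- normalize_expression(filter_low_expression(sim$expr))
  corr <- correlate_dmps(dmps, mf, en, sim$annotation)

  expect_true(all(corr$p < 0.05))
  expect_equal(corr$sign, ifelse(corr$rho < 0, "negative", "positive"))
  coup <- sim$truth_probes[!is.na(sim$truth_probes$coupled_gene), ]
  key <- paste(corr$probe_id, corr$gene)
  ck <- paste(coup$probe_id, coup$coupled_gene)
  hit <- ck %in% key
  expect_gt(mean(hit), 0.5)
  m <- match(ck[hit], key)
  agree <- (corr$sign[m] == "negative") == (coup$coupling_sign[hit] == -1)
  expect_gte(mean(agree), 0.95)

  # a probe annotated to a gene absent from the expression set yields no
  # record and is counted as skipped
  ann2 <- sim$annotation
  ann2$gene_map$gene[ann2$gene_map$probe_id == dmps$probe_id[1]] <- "ABSENT1"
  corr2 <- correlate_dmps(dmps, mf, en, ann2)
  expect_false(any(corr2$gene == "ABSENT1"))
  expect_gte(attr(corr2, "skipped")[["gene_missing"]], 1)
})

test_that("null coupling: emission rate of the alpha screen is binomial-consistent", {
  nsim <- simulate_dataset(sim_config(frac_dmp = 0, frac_deg = 0,
                                      coupling_strength = 0, seed = 11))
  mf <- filter_probes(nsim$meth, nsim$annotation)
  en <- normalize_expression(filter_low_expression(nsim$expr))
  pseudo_dmps <- data.frame(probe_id = rownames(mf$beta),
                            direction = "hyper")
  corr <- correlate_dmps(pseudo_dmps, mf, en, nsim$annotation)
  n <- attr(corr, "n_tested")
  expect_gt(n, 1000)
  lo <- qbinom(0.005, n, 0.05)
  hi <- qbinom(0.995, n, 0.05)
  expect_gte(nrow(corr), lo)
  expect_lte(nrow(corr), hi)
})

test_that("correlate_dmps is invariant to joint permutation of tumor samples", {
  sim <- small_sim(seed = 2)
  mf <- filter_probes(sim$meth, sim$annotation)
  dmps <- call_dmps(mf, sim$annotation)
  en <- normalize_expression(filter_low_expression(sim$expr))
  base <- correlate_dmps(dmps, mf, en, sim$annotation)

  set.seed(99)
  perm <- c(sample(1:32), 33:37)
  samples2 <- mf$samples[perm, ]
  mf2 <- meth_set(mf$beta[, perm], samples2)
  en2 <- expr_set(en$counts[, perm], samples2,
                  size_factors = en$size_factors[perm])
  permd <- correlate_dmps(dmps, mf2, en2, sim$annotation)
  expect_equal(permd$rho, base$rho, tolerance = 1e-12)
  expect_equal(permd$probe_id, base$probe_id)
})

test_that("ratio_test: homogeneity, back-solved printed ratios, chi-square oracle", {
  homog <- data.frame(
    sign = rep(c("negative", "positive"), each = 20),
    region_class = rep(rep(c("body", "promoter"), each = 10), 2)
  )
  rt <- ratio_test(homog)
  expect_equal(rt$ratio_negative, 1)
  expect_equal(rt$ratio_positive, 1)
  expect_equal(rt$chi2_p, 1)

  # counts reconstructed from the published totals: 1756 negative with
  # body:promoter 1.36 -> (1012, 744); 767 positive with 2.5 -> (548, 219)
  printed <- data.frame(
    sign = rep(c("negative", "positive"), c(1756, 767)),
    region_class = c(rep(c("body", "promoter"), c(1012, 744)),
                     rep(c("body", "promoter"), c(548, 219)))
  )
  rt <- ratio_test(printed)
  expect_equal(round(rt$ratio_negative, 2), 1.36)
  expect_equal(round(rt$ratio_positive, 2), 2.50)
  expect_lt(rt$chi2_p, 0.00001)

  set.seed(17)
  for (rep in 1:20) {
    k <- rpois(4, 30) + 1  # neg-body, neg-prom, pos-body, pos-prom
    df <- data.frame(
      sign = rep(c("negative", "negative", "positive", "positive"), k),
      region_class = rep(c("body", "promoter", "body", "promoter"), k)
    )
    rt <- ratio_test(df)
    orc <- oracle_chisq(matrix(k, 2, 2, byrow = TRUE))
    expect_equal(rt$chi2, unname(orc["stat"]), tolerance = 1e-12)
    expect_equal(rt$chi2_p, unname(orc["p"]), tolerance = 1e-12)
  }

  # zero promoter count: infinite ratio, chi-square still returned
  zp <- data.frame(sign = rep(c("negative", "positive"), each = 4),
                   region_class = c(rep("body", 4),
                                    rep(c("body", "promoter"), 2)))
  rt <- ratio_test(zp)
  expect_equal(rt$ratio_negative, Inf)
  expect_true(is.finite(rt$chi2))
})

test_that("quadrant classification: printed cases, exhaustion, double-flip symmetry", {
  expect_true(classify_quadrant("hyper", "negative", "down"))
  expect_true(classify_quadrant("hypo", "negative", "up"))
  expect_true(classify_quadrant("hyper", "positive", "up"))
  expect_true(classify_quadrant("hypo", "positive", "down"))

  grid <- expand.grid(m = c("hyper", "hypo"), s = c("negative", "positive"),
                      e = c("up", "down"), stringsAsFactors = FALSE)
  conc <- classify_quadrant(grid$m, grid$s, grid$e)
  expect_equal(sum(conc), 4L)
  expect_equal(sum(!conc), 4L)
  flip <- classify_quadrant(ifelse(grid$m == "hyper", "hypo", "hyper"),
                            grid$s,
                            ifelse(grid$e == "up", "down", "up"))
  expect_equal(conc, flip)
  expect_error(classify_quadrant("hyper", "neg", "up"))
})

test_that("overlap_with_degs is a sound inner join", {
  corr <- data.frame(
    probe_id = paste0("cg", 1:5),
    gene = paste0("G", 1:5),
    sign = c("negative", "negative", "positive", "negative", "positive"),
    stringsAsFactors = FALSE
  )
  dmps <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                     direction = c("hyper", "hypo", "hyper"))
  degs <- data.frame(gene = c("G1", "G3", "G9"),
                     direction = c("down", "up", "up"))
  q <- overlap_with_degs(corr, dmps, degs)
  expect_equal(nrow(q), 2L)  # only (cg1,G1) and (cg3,G3) are in all three
  expect_setequal(q$probe_id, c("cg1", "cg3"))
  expect_equal(q$concordant, c(TRUE, TRUE))

  empty <- overlap_with_degs(corr, dmps, degs[0, ])
  expect_equal(nrow(empty), 0L)

  # on simulated data every emitted pair exists in all three inputs
  sim <- small_sim(seed = 3)
  mf <- filter_probes(sim$meth, sim$annotation)
  dmps <- call_dmps(mf, sim$annotation)
  en <- normalize_expression(filter_low_expression(sim$expr))
  cr <- correlate_dmps(dmps, mf, en, sim$annotation)
  qq <- overlap_with_degs(cr, dmps, call_degs(en))
  expect_true(all(qq$probe_id %in% dmps$probe_id))
  expect_true(all(qq$gene %in% call_degs(en)$gene))
  expect_true(all(paste(qq$probe_id, qq$gene) %in% paste(cr$probe_id, cr$gene)))
})

test_that("integration_summary: identities and printed-percentage arithmetic", {
  # 2523 significant probes out of 23022 tested -> 11.0%
  corr <- data.frame(
    probe_id = sprintf("cg%05d", 1:2523),
    gene = sprintf("G%04d", rep(1:1470, length.out = 2523)),
    rho = c(rep(-0.463, 1756), rep(0.448, 767)),
    p = 0.01,
    sign = rep(c("negative", "positive"), c(1756, 767)),
    stringsAsFactors = FALSE
  )
  s <- integration_summary(corr, n_tested = 23022)
  expect_equal(s$pct_significant, 11.0)
  expect_equal(s$n_negative, 1756)
  expect_equal(s$n_positive, 767)
  expect_equal(s$n_negative + s$n_positive, s$n_significant)
  expect_equal(s$n_genes, 1470)
  expect_equal(s$median_rho_negative, -0.463)

  empty <- integration_summary(corr[0, ], n_tested = 100)
  expect_equal(empty$n_significant, 0L)
  expect_equal(empty$pct_significant, 0)

  # quadrant counts sum to the pair count
  sim <- small_sim(seed = 4)
  mf <- filter_probes(sim$meth, sim$annotation)
  dmps <- call_dmps(mf, sim$annotation)
  en <- normalize_expression(filter_low_expression(sim$expr))
  cr <- correlate_dmps(dmps, mf, en, sim$annotation)
  qq <- overlap_with_degs(cr, dmps, call_degs(en))
  s2 <- integration_summary(cr, qq)
  expect_equal(sum(s2$quadrant_counts), nrow(qq))
})
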