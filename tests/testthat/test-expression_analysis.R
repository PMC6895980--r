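# Count filtering, size factors, fold change, the NB Wald test and DEG
# calling.

test_that("low-expression filter keeps genes with enough reads in enough samples", {
  samples <- toy_samples()
  counts <- rbind(
    zero = c(0L, 0L, 0L, 0L),
    boundary = c(5L, 5L, 0L, 0L),   # 5 reads in exactly half the samples
    below = c(4L, 4L, 4L, 0L),
    high = c(100L, 80L, 90L, 70L),
    lop = c(9L, 0L, 0L, 0L),
    two = c(6L, 0L, 7L, 0L)
  )
  colnames(counts) <- samples$sample_id
  es <- expr_set(counts, samples)
  kept <- filter_low_expression(es)
  expect_setequal(rownames(kept$counts), c("boundary", "high", "two"))
})

test_that("size factors: identities, oracle equality and DESeq2 agreement", {
  samples <- toy_samples()
  base <- matrix(rpois(200, 60) + 1L, 50, 4,
                 dimnames = list(paste0("G", 1:50), samples$sample_id))
  # two identical columns -> equal factors
  eq <- base; eq[, 2] <- eq[, 1]
  sf <- estimate_size_factors(expr_set(eq, samples))
  expect_equal(sf[[1]], sf[[2]], tolerance = 1e-12)
  # column2 = 2 x column1 -> factor ratio 2
  dbl <- base; dbl[, 2] <- 2L * dbl[, 1]
  sf <- estimate_size_factors(expr_set(dbl, samples))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rnbinom(200, mu = 80, size = 5), 50, 4,
                dimnames = list(paste0("G", 1:50), samples$sample_id))
    m[m == 0] <- 1L
    es <- expr_set(m, samples)
    expect_equal(unname(estimate_size_factors(es)), oracle_size_factors(m),
                 tolerance = 1e-12)
  }

  # independent established implementation agrees up to a common rescaling
  # (odd gene count: the two median conventions coincide exactly)
  m <- matrix(rnbinom(404, mu = 100, size = 5) + 1L, 101, 4,
              dimnames = list(paste0("G", 1:101), samples$sample_id))
  ours <- estimate_size_factors(expr_set(m, samples))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ref), rep(mean(ours / ref), 4),
               tolerance = 1e-8)

  # scale equivariance: multiplying one column by c multiplies its factor by c
  m2 <- m; m2[, 3] <- m2[, 3] * 3L
  sf2 <- estimate_size_factors(expr_set(m2, samples))
  expect_equal(unname((sf2 / ours)[3] / (sf2 / ours)[1]), 3,
               tolerance = 1e-12)

  # all-zero gene in some sample everywhere -> error when nothing survives
  zeros <- matrix(0L, 2, 4, dimnames = list(c("a", "b"), samples$sample_id))
  expect_error(estimate_size_factors(expr_set(zeros, samples)),
               "cannot normalize")
})

test_that("fold change: arithmetic, pseudocount contract, degenerate input", {
  samples <- toy_samples()
  counts <- rbind(equal = c(10L, 10L, 10L, 10L),
                  twofold = c(10L, 10L, 5L, 5L),
                  silent = c(0L, 0L, 0L, 0L))
  colnames(counts) <- samples$sample_id
  es <- expr_set(counts, samples, size_factors = rep(1, 4))
  fc <- fold_change(es, pseudocount = 0)
  expect_equal(unname(fc["equal"]), 1)
  expect_equal(unname(fc["twofold"]), 2)
  fc <- fold_change(es)  # pseudocount 0.5
  expect_equal(unname(fc["silent"]), 1)
})

test_that("deg_test conventions and null calibration", {
  samples <- toy_samples()
  counts <- rbind(zero = c(0L, 0L, 0L, 0L), ok = c(5L, 6L, 7L, 8L))
  colnames(counts) <- samples$sample_id
  es <- expr_set(counts, samples, size_factors = rep(1, 4))
  res <- deg_test(es)
  expect_equal(res$p[res$gene == "zero"], 1)

  # type-I error near nominal on a null simulation
  nsim <- simulate_dataset(sim_config(frac_dmp = 0, frac_deg = 0,
                                      coupling_strength = 0, seed = 13))
  en <- normalize_expression(filter_low_expression(nsim$expr))
  tst <- deg_test(en)
  rate <- mean(tst$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("call_degs recovers planted 4-fold genes and stays quiet on null data", {
  sim <- simulate_dataset(sim_config(seed = 1))
  en <- normalize_expression(filter_low_expression(sim$expr))
  degs <- call_degs(en)
  tg <- sim$truth_genes
  planted <- tg$gene[tg$is_deg]
  expect_gte(mean(planted %in% degs$gene), 0.9)
  # realized FDR on truth at the called set
  m <- match(degs$gene, tg$gene)
  expect_lte(mean(!tg$is_deg[m]), 0.1)
  called_planted <- tg$is_deg[m]
  expect_gte(mean(degs$direction[called_planted] ==
                    tg$true_direction[m][called_planted]), 0.99)
  expect_true(all(degs$fold_change > 2 | degs$fold_change < 0.5))

  nsim <- simulate_dataset(sim_config(frac_dmp = 0, frac_deg = 0,
                                      coupling_strength = 0, seed = 11))
  nen <- normalize_expression(filter_low_expression(nsim$expr))
  expect_lte(nrow(call_degs(nen)), 1L)

  # unreachable fold-change threshold -> no calls
  expect_equal(nrow(call_degs(en, deg_thresholds(min_fc = 1e6))), 0L)
})

test_that("swapping group labels inverts fold change and flips directions", {
  sim <- small_sim(seed = 8)
  en <- normalize_expression(filter_low_expression(sim$expr))
  degs <- call_degs(en)
  flipped_samples <- en$samples
  flipped_samples$group <- ifelse(flipped_samples$group == "tumor",
                                  "normal", "tumor")
  en_f <- expr_set(en$counts, flipped_samples, size_factors = en$size_factors)
  fc <- fold_change(en)
  fc_f <- fold_change(en_f)
  # exact reciprocal at pseudocount 0 on the shared support
  fc0 <- fold_change(en, pseudocount = 0)
  fc0_f <- fold_change(en_f, pseudocount = 0)
  expect_equal(unname(fc0_f), unname(1 / fc0), tolerance = 1e-12)
  degs_f <- call_degs(en_f)
  both <- intersect(degs$gene, degs_f$gene)
  expect_gt(length(both), 0)
  expect_true(all(degs$direction[match(both, degs$gene)] !=
                    degs_f$direction[match(both, degs_f$gene)]))
})
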