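# Probe filtering, the M transform, delta-beta, the per-probe tests, DMP
# calling and the composition report.

test_that("filter_probes applies the sex/SNP/multimap/detection rules", {
  samples <- toy_samples()
  ids <- paste0("cg", 1:10)
  beta <- matrix(0.5, 10, 4, dimnames = list(ids, samples$sample_id))
  ann <- toy_annotation(ids, genes = paste0("G", 1:10),
                        chrom = c("chrX", "chrX", rep("chr1", 8)),
                        snp = c(rep(FALSE, 2), TRUE, rep(FALSE, 7)))
  det <- matrix(0.001, 10, 4, dimnames = dimnames(beta))
  det["cg4", 2] <- 0.02  # one failing detection value
  ms <- meth_set(beta, samples, detection_p = det)
  kept <- filter_probes(ms, ann)
  expect_equal(rownames(kept$beta), paste0("cg", 5:10))  # 6 retained
  # clean probe with passing detection values is retained
  expect_true("cg5" %in% rownames(kept$beta))
  # order preserved
  expect_equal(rownames(kept$beta), ids[ids %in% rownames(kept$beta)])
  # probe missing from annotation is an error naming it
  ann2 <- toy_annotation(ids[-1], genes = paste0("G", 2:10))
  expect_error(filter_probes(ms, ann2), "cg1")
})

test_that("m_values is the clipped logit2 transform", {
  expect_equal(m_values(0.5), 0)
  expect_equal(m_values(0.8), 2)
  eps <- 1e-6
  expect_equal(m_values(0), log2(eps / (1 - eps)))
  expect_true(is.finite(m_values(1)))
})

test_that("delta_beta equals the brute-force per-row group-mean difference", {
  ms <- toy_meth(list(cg1 = c(0.8, 0.8, 0.5, 0.5),
                      cg2 = c(0.3, 0.3, 0.3, 0.3)))
  db <- delta_beta(ms)
  expect_equal(unname(db["cg1"]), 0.3)
  expect_equal(unname(db["cg2"]), 0)

  set.seed(42)
  samples <- toy_samples(5, 4)
  beta <- matrix(runif(90), 10, 9,
                 dimnames = list(paste0("cg", 1:10), samples$sample_id))
  ms <- meth_set(beta, samples)
  db <- delta_beta(ms)
  for (i in 1:10) {
    expect_equal(unname(db[i]),
                 mean(beta[i, 1:5]) - mean(beta[i, 6:9]), tolerance = 1e-12)
  }
})

test_that("dmp_test matches t.test per probe and honors the degenerate conventions", {
  samples <- toy_samples(3, 3)
  beta <- rbind(
    cg_const = rep(0.5, 6),                       # both groups identical constants
    cg_same  = c(0.6, 0.7, 0.8, 0.6, 0.7, 0.8),   # same values both groups
    cg_sep   = c(0.85, 0.87, 0.86, 0.51, 0.49, 0.50)  # strong separation
  )
  colnames(beta) <- samples$sample_id
  ms <- meth_set(beta, samples)
  res <- dmp_test(ms)
  expect_equal(res$p[res$probe_id == "cg_const"], 1)
  expect_equal(res$stat[res$probe_id == "cg_same"], 0)
  expect_equal(res$p[res$probe_id == "cg_same"], 1)
  expect_lt(res$p[res$probe_id == "cg_sep"], 0.001)

  m <- m_values(ms)
  wt <- t.test(m["cg_sep", 1:3], m["cg_sep", 4:6])
  expect_equal(res$stat[res$probe_id == "cg_sep"], unname(wt$statistic),
               tolerance = 1e-10)
  expect_equal(res$p[res$probe_id == "cg_sep"], wt$p.value,
               tolerance = 1e-10)
})

test_that("bh_adjust equals the step-up oracle and p.adjust on random vectors", {
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in raw p
  }
})

test_that("call_dmps recovers planted DMPs and respects impossible thresholds", {
  sim <- simulate_dataset(sim_config(seed = 1))
  mf <- filter_probes(sim$meth, sim$annotation)
  dmps <- call_dmps(mf, sim$annotation)
  tp <- sim$truth_probes
  planted <- tp$probe_id[tp$is_dmp]
  expect_gte(mean(planted %in% dmps$probe_id), 0.9)
  m <- match(dmps$probe_id, tp$probe_id)
  called_planted <- tp$is_dmp[m]
  expect_gte(mean(dmps$direction[called_planted] ==
                    tp$true_direction[m][called_planted]), 0.99)
  # direction is the delta-beta sign, record by record
  expect_equal(dmps$direction, ifelse(dmps$delta_beta > 0, "hyper", "hypo"))
  expect_true(all(abs(dmps$delta_beta) > 0.2))
  expect_true(all(dmps$adj_p <= 0.005))

  expect_error(dmp_thresholds(min_abs_delta_beta = 1.1))
  tiny <- dmp_thresholds(min_abs_delta_beta = 0.999)
  expect_equal(nrow(call_dmps(mf, sim$annotation, tiny)), 0L)
})

test_that("null cohort yields no DMP calls", {
  nsim <- simulate_dataset(sim_config(frac_dmp = 0, frac_deg = 0,
                                      coupling_strength = 0, seed = 11))
  mf <- filter_probes(nsim$meth, nsim$annotation)
  expect_equal(nrow(call_dmps(mf, nsim$annotation)), 0L)
})

test_that("call_dmps is invariant to probe order and sample order within groups", {
  sim <- small_sim(seed = 6)
  mf <- filter_probes(sim$meth, sim$annotation)
  base <- call_dmps(mf, sim$annotation)

  perm <- sample(nrow(mf$beta))
  ms_p <- meth_set(mf$beta[perm, , drop = FALSE], mf$samples)
  shuffled <- call_dmps(ms_p, sim$annotation)
  expect_equal(shuffled[order(shuffled$probe_id), ],
               base[order(base$probe_id), ], ignore_attr = TRUE)

  sperm <- c(sample(1:32), sample(33:37))
  samples2 <- mf$samples[sperm, ]
  ms_s <- meth_set(mf$beta[, sperm, drop = FALSE], samples2)
  expect_equal(call_dmps(ms_s, sim$annotation), base, ignore_attr = TRUE)
})

test_that("composition_report reproduces printed-style percentages", {
  # directions alone: counts mirroring the published DMP composition
  ids <- sprintf("cg%05d", 1:23022)
  ann <- toy_annotation(ids, genes = sprintf("G%05d", 1:23022))
  records <- data.frame(
    probe_id = ids,
    direction = rep(c("hyper", "hypo"), c(19658, 3364)),
    stringsAsFactors = FALSE
  )
  rep_out <- composition_report(records, ann)
  dir_tab <- rep_out$direction
  expect_equal(dir_tab$pct[dir_tab$category == "hyper"], 85.4)
  expect_equal(dir_tab$pct[dir_tab$category == "hypo"], 14.6)

  # single-category input reports 100.0%
  one <- composition_report(records[records$direction == "hyper", ], ann)
  expect_equal(one$direction$pct, 100.0)
})

test_that("region tally counts one per annotated (gene, region) pair", {
  ids <- c("cg1", "cg2")
  probes <- data.frame(probe_id = ids, chrom = "chr1", pos = c(1, 2),
                       cpg_context = c("Island", "OpenSea"),
                       snp_flag = FALSE, multimap_flag = FALSE)
  gm <- data.frame(probe_id = c("cg1", "cg1", "cg2"),
                   gene = c("A", "B", "C"),
                   region = c("TSS200", "Body", "Body"))
  ann <- probe_annotation(probes, gm)
  records <- data.frame(probe_id = ids, direction = c("hyper", "hypo"))
  rep_out <- composition_report(records, ann)
  reg <- rep_out$region
  expect_equal(reg$count[reg$category == "promoter"], 1L)
  expect_equal(reg$count[reg$category == "body"], 2L)
  ctx <- rep_out$context
  expect_equal(sum(ctx$count), 2L)  # context counts once per probe
})

test_that("round_half_up rounds ties away from zero at one decimal", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(85.35, 1), 85.4)
  expect_equal(round_half_up(85.34, 1), 85.3)
  expect_equal(percent_of(19658, 23022), 85.4)
})
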