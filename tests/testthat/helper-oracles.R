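# Independent brute-force oracles used to pin down the statistical
# primitives. Each is written as directly as possible from the defining
# formula (loops, enumeration, choose()), deliberately avoiding the code
# paths it checks.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, ps[j] * n / j)
    q[i] <- min(m, 1)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_hyper_tail <- function(k, K, N, n) {
  # P(overlap >= k) with K marked among N, drawing n
  kk <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  prob_a <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  p_obs <- prob_a(a)
  xs <- lo:hi
  sum(vapply(xs, prob_a, 0)[vapply(xs, prob_a, 0) <= p_obs * (1 + 1e-7)])
}

oracle_mw_exact_p <- function(x, y) {
  # exact two-sided Mann-Whitney p by enumerating all rank splits
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  sub <- counts[keep, , drop = FALSE]
  geo <- apply(sub, 1, function(g) exp(mean(log(g))))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    sf[j] <- stats::median(sub[, j] / geo)
  sf / exp(mean(log(sf)))
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  c(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}
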