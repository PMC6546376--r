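# Independent brute-force reference implementations used as oracles.
# These are deliberately naive (O(n^2) loops, direct formulas) and share no
# code with the package internals.

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# haplotype r2 from two-locus haplotype frequencies
oracle_r2 <- function(a, b) {
  n <- length(a)
  pA <- sum(a) / n; pB <- sum(b) / n
  pAB <- sum(a == 1 & b == 1) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

# pi over [start, start+window) by explicit pairwise comparison
oracle_pi_window <- function(alleles, pos, start, window, L) {
  n <- nrow(alleles)
  end <- min(start + window, L)
  sites <- which(pos >= start & pos < start + window)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(alleles[i, sites] != alleles[j, sites])
  tot / (n * (n - 1) / 2) / (end - start)
}

# EHHS at every site by explicit pairwise identity over the interval
# between the focal site (excluded) and the evaluation site (included)
oracle_ehhs <- function(alleles, pos, focal) {
  n <- nrow(alleles); m <- ncol(alleles)
  npairs <- n * (n - 1) / 2
  vals <- numeric(m)
  for (t in seq_len(m)) {
    if (t == focal) { vals[t] <- 1; next }
    rng <- if (t > focal) (focal + 1):t else t:(focal - 1)
    id <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (all(alleles[i, rng] == alleles[j, rng])) id <- id + 1
    vals[t] <- id / npairs
  }
  data.frame(position = pos, dist = pos - pos[focal], ehhs = vals)
}

# trapezoid integral of the EHHS curve in both directions, truncating after
# the first sub-threshold point, extending the outermost value to [0, L)
oracle_ies_at <- function(alleles, pos, focal, L, truncation = 0.05) {
  cur <- oracle_ehhs(alleles, pos, focal)
  total <- 0
  for (dirn in c(1, -1)) {
    idx <- if (dirn == 1) which(cur$dist > 0) else rev(which(cur$dist < 0))
    prev_val <- 1; prev_pos <- pos[focal]
    truncated <- FALSE
    for (t in idx) {
      total <- total + (prev_val + cur$ehhs[t]) / 2 * abs(cur$position[t] - prev_pos)
      prev_val <- cur$ehhs[t]; prev_pos <- cur$position[t]
      if (cur$ehhs[t] < truncation) { truncated <- TRUE; break }
    }
    if (!truncated)
      total <- total + prev_val * abs((if (dirn == 1) L else 0) - prev_pos)
  }
  total / 1e6
}

# per-cut standardized statistics by direct two-group computation
oracle_cut_stats <- function(year, y, minprop = 0.1, maxprop = 0.9) {
  yrs <- sort(unique(year))
  N <- length(y)
  ybar <- mean(y)
  v <- mean((y - ybar)^2)
  out <- data.frame(left_year = yrs[-length(yrs)], stat = NA_real_,
                    eligible = NA)
  for (k in seq_len(length(yrs) - 1)) {
    sel <- year <= yrs[k]
    nl <- sum(sel)
    out$eligible[k] <- nl >= minprop * N & nl <= maxprop * N
    S <- sum(y[sel])
    out$stat[k] <- (S - nl * ybar) / sqrt(nl * (N - nl) / (N - 1) * v)
  }
  out
}

# neutral SFS goodness of fit against the 1/i coalescent expectation:
# Hotelling's T2 on binned per-replicate SFS compositions (replicates are
# the sampling unit; one bin dropped for the composition constraint)
sfs_gof_p <- function(seeds, n = 20,
                      bins = list(1, 2, 3:4, 5:8, 9:19)) {
  P <- t(vapply(seeds, function(s) {
    p <- forward_sim_params(N = 200, L = 2e5, mu = 1.25e-6,
                            map = recombination_map(0, 2e5, 2.5e-6, 2e5),
                            dfe = dfe_config(p_deleterious = 0),
                            burnin = 2000, sample_n = n, seed = s)
    dac <- colSums(run_simulation(p)$hap$alleles)
    dac <- dac[dac > 0 & dac < n]
    cnt <- tabulate(dac, nbins = n - 1)
    vapply(bins, function(b) sum(cnt[b]), 0) / sum(cnt)
  }, numeric(length(bins))))
  exp_full <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  mu0 <- vapply(bins, function(b) sum(exp_full[b]), 0)
  X <- P[, -length(bins), drop = FALSE]
  m0 <- mu0[-length(bins)]
  R <- nrow(X); d <- ncol(X)
  T2 <- R * t(colMeans(X) - m0) %*% solve(cov(X)) %*% (colMeans(X) - m0)
  as.numeric(pf((R - d) / (d * (R - 1)) * T2, d, R - d, lower.tail = FALSE))
}

# small toy haplotype fixture: n_hap x n_sites random binary with distinct
# positions, guaranteed polymorphic columns
random_hap <- function(n_hap, n_sites, L = 1e5, seed = 1) {
  set.seed(seed)
  a <- matrix(rbinom(n_hap * n_sites, 1, runif(n_sites, 0.2, 0.8)[
    rep(seq_len(n_sites), each = n_hap)]), n_hap, n_sites)
  for (j in seq_len(n_sites)) {     # force polymorphism
    if (all(a[, j] == a[1, j])) a[sample(n_hap, 1), j] <- 1 - a[1, j]
  }
  pos <- sort(sample.int(L - 1, n_sites))
  haplotype_matrix(a, pos, chrom = "1", chrom_length = L)
}
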