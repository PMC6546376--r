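test_that("pairwise r2 matches haplotype-frequency arithmetic", {
  # two-locus counts (3,1,1,3) over 8 haplotypes: D = 0.125, r2 = 0.25
  a <- c(0, 0, 0, 0, 1, 1, 1, 1)
  b <- c(0, 0, 0, 1, 0, 1, 1, 1)
  hap <- haplotype_matrix(cbind(a, b), c(10, 20), chrom_length = 100)
  expect_equal(pairwise_r2(hap, 1, 2), 0.25, tolerance = 1e-12)
  expect_equal(pairwise_r2(hap, 1, 1), 1)

  # four haplotypes 00, 01, 10, 11 equally frequent: independence
  hap2 <- haplotype_matrix(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)), c(1, 2),
                           chrom_length = 10)
  expect_equal(pairwise_r2(hap2, 1, 2), 0)

  # monomorphic site is masked
  hap3 <- haplotype_matrix(cbind(c(1, 1, 1, 1), c(0, 1, 0, 1)), c(1, 2),
                           chrom_length = 10)
  expect_true(is.na(pairwise_r2(hap3, 1, 2)))

  # oracle equivalence on random fixtures
  hap4 <- random_hap(16, 30, seed = 2)
  for (k in 1:25) {
    ij <- sample(30, 2)
    expect_equal(pairwise_r2(hap4, ij[1], ij[2]),
                 oracle_r2(hap4$alleles[, ij[1]], hap4$alleles[, ij[2]]),
                 tolerance = 1e-10)
  }
})

test_that("hudson FST matches the closed form and masks degenerate sites", {
  # worked value: n1 = n2 = 50 haploid genomes, p1 = 0.6, p2 = 0.4
  expect_equal(round(oracle_hudson_fst(0.6, 0.4, 50, 50), 4), 0.0581)
  # realize those exact frequencies as dosages (25 diploids per pop)
  d1 <- c(rep(2, 15), rep(0, 10))           # 30/50 alt alleles
  d2 <- c(rep(2, 10), rep(0, 15))           # 20/50
  geno <- genotype_matrix(cbind(d1val = c(d1, d2)), positions = 5,
                          pop_labels = rep(c("p1", "p2"), each = 25))
  fst <- hudson_fst_per_snp(geno)
  expect_equal(fst$raw, oracle_hudson_fst(0.6, 0.4, 50, 50),
               tolerance = 1e-10)
  expect_equal(round(fst$raw, 4), 0.0581)

  # fixed difference: FST = 1
  g2 <- genotype_matrix(cbind(c(rep(2, 5), rep(0, 5))), positions = 1,
                        pop_labels = rep(c("a", "b"), each = 5))
  expect_equal(hudson_fst_per_snp(g2)$raw, 1)

  # monomorphic in both pops: masked
  g3 <- genotype_matrix(cbind(rep(2, 10), rep(0, 10)), positions = 1:2,
                        pop_labels = rep(c("a", "b"), each = 5))
  expect_true(all(is.na(hudson_fst_per_snp(g3)$raw)))

  # null calibration: equal frequencies give expectation <= 0
  set.seed(31)
  m <- 4000
  p <- runif(m, 0.2, 0.8)
  dos <- vapply(p, function(pp) rbinom(40, 2, pp), integer(40))
  g4 <- genotype_matrix(dos, seq_len(m),
                        pop_labels = rep(c("a", "b"), each = 20))
  expect_lt(abs(mean(hudson_fst_per_snp(g4)$raw, na.rm = TRUE)), 0.01)
})

test_that("r2, FST and pi are invariant to allele relabeling", {
  hap <- random_hap(12, 20, seed = 6)
  swapped <- haplotype_matrix(1L - hap$alleles, hap$positions,
                              chrom_length = hap$chrom_length)
  expect_equal(pairwise_r2(hap, 3, 9), pairwise_r2(swapped, 3, 9),
               tolerance = 1e-12)
  expect_equal(pi_windows(hap, 1e4)$raw, pi_windows(swapped, 1e4)$raw,
               tolerance = 1e-12)
  g <- hap_to_geno(hap, pop_labels = rep(c("a", "b"), 3))
  gs <- hap_to_geno(swapped, pop_labels = rep(c("a", "b"), 3))
  expect_equal(hudson_fst_per_snp(g)$raw, hudson_fst_per_snp(gs)$raw,
               tolerance = 1e-12)
})

test_that("pi windows match pairwise enumeration and sum to the total", {
  # 4 haplotypes, 2 sites each with a 2/2 split in a 1 kb window
  a <- cbind(c(0, 0, 1, 1), c(1, 1, 0, 0))
  hap <- haplotype_matrix(a, c(100, 600), chrom_length = 1000)
  pw <- pi_windows(hap, window = 1000)
  expect_equal(pw$raw, 8 / 6 / 1000, tolerance = 1e-12)
  expect_equal(round(pw$raw, 6), 0.001333)

  # monomorphic window
  hap0 <- haplotype_matrix(matrix(c(1, 1, 1, 1), 4, 1), 50,
                           chrom_length = 1000)
  expect_equal(pi_windows(hap0, 1000)$raw, 0)

  # oracle equivalence + length-weighted window sums = chromosome-wide pi
  hap2 <- random_hap(14, 40, L = 9500, seed = 8)
  pw2 <- pi_windows(hap2, window = 2000)
  for (w in seq_along(pw2$raw)) {
    start <- (w - 1) * 2000
    expect_equal(pw2$raw[w],
                 oracle_pi_window(hap2$alleles, hap2$positions, start, 2000,
                                  9500),
                 tolerance = 1e-10)
  }
  lens <- diff(c(seq(0, 9500 - 1, by = 2000), 9500))
  expect_equal(sum(pw2$raw * lens) / 9500, pi_total(hap2), tolerance = 1e-12)
})

test_that("EHHS is 1 at the focal site, matches enumeration, and decays", {
  # groups {2,1,1} at the second site out: EHHS = 1/6
  a <- cbind(c(0, 0, 1, 1),         # focal
             c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  hap <- haplotype_matrix(a, c(0, 50, 120), chrom_length = 1000)
  e <- ehhs_curve(hap, 1)
  expect_equal(e$ehhs[e$dist == 0], 1)
  expect_equal(e$ehhs[e$dist == 120], 1 / 6, tolerance = 1e-12)

  # haplotypes identical everywhere but the (excluded) focal site:
  # EHHS = 1 at every distance
  al <- matrix(0L, 4, 5)
  al[, 3] <- c(0L, 0L, 1L, 1L)
  hap1 <- haplotype_matrix(al, seq(0, 400, 100), chrom_length = 1000)
  expect_true(all(ehhs_curve(hap1, 3)$ehhs == 1))

  # enumeration oracle + monotone decay on random fixtures
  for (s in 1:4) {
    hap2 <- random_hap(10, 15, L = 2000, seed = s)
    f <- sample(15, 1)
    e2 <- ehhs_curve(hap2, f)
    o <- oracle_ehhs(hap2$alleles, hap2$positions, f)
    expect_equal(e2$ehhs, o$ehhs, tolerance = 1e-10)
    right <- e2$ehhs[e2$dist >= 0]
    left <- rev(e2$ehhs[e2$dist <= 0])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
  }
})

test_that("iES integrates EHHS by trapezoid with truncation and edges", {
  # two constant haplotype groups: EHHS stays at 1/3 >= truncation, so the
  # integral runs to both chromosome ends; upper bound ~ L (in Mb)
  hapc <- haplotype_matrix(matrix(rep(c(0, 0, 1, 1), 3), 4, 3),
                           c(100, 500, 900), chrom_length = 2e6)
  iesc <- ies_scan(hapc)
  for (f in 1:3)
    expect_equal(iesc$raw[f],
                 oracle_ies_at(hapc$alleles, hapc$positions, f, 2e6),
                 tolerance = 1e-10)
  # sanity: close to EHHS-plateau * chromosome length
  expect_gt(min(iesc$raw), (1 / 3) * 2)
  expect_lt(max(iesc$raw), 2)

  # oracle equivalence on random fixtures (includes truncation paths)
  hap2 <- random_hap(8, 20, L = 5e4, seed = 13)
  ies2 <- ies_scan(hap2, truncation = 0.05)
  for (f in c(1, 5, 10, 20))
    expect_equal(ies2$raw[f],
                 oracle_ies_at(hap2$alleles, hap2$positions, f, 5e4),
                 tolerance = 1e-10)
})

test_that("LD decay and long-distance track average the right pairs", {
  # single eligible pair with known r2 = 1
  a <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1))
  hap <- haplotype_matrix(a, c(0, 3000), chrom_length = 10000)
  ld <- ld_decay_curve(hap, max_dist = 5000, n_bins = 5, maf = 0)
  expect_equal(sum(ld$meta$n_pairs), 1)
  expect_equal(ld$raw[!is.na(ld$raw)], 1)

  # hand average inside a window
  set.seed(17)
  hap2 <- random_hap(20, 12, L = 60e3, seed = 17)
  tr <- long_distance_ld_track(hap2, window = 60e3, step = 60e3,
                               min_sep = 5e3, max_sep = 50e3, maf = 0)
  pos <- hap2$positions
  r2s <- c(); mids <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    d <- pos[j] - pos[i]
    if (d >= 5e3 && d <= 50e3) {
      r2s <- c(r2s, oracle_r2(hap2$alleles[, i], hap2$alleles[, j]))
      mids <- c(mids, (pos[i] + pos[j]) / 2)
    }
  }
  expect_equal(tr$raw[1], mean(r2s[mids < 60e3]), tolerance = 1e-10)

  # all pairs closer than min_sep: track entirely missing
  hap3 <- random_hap(10, 5, L = 1e3, seed = 3)
  hap3$chrom_length <- 300e3
  tr3 <- long_distance_ld_track(hap3, window = 100e3, step = 100e3,
                                min_sep = 20e3, max_sep = 200e3, maf = 0)
  expect_true(all(is.na(tr3$raw)))
})

test_that("eigenGWAS separates structured populations and is stable", {
  set.seed(23)
  g <- generate_structured_genotypes(
    structured_pop_config(n_per_pop = 60, n_snps = 800, fst_target = 0.1,
                          seed = 23))
  res <- eigengwas_scan(g$geno)
  lab <- as.integer(factor(g$geno$pop_labels))
  expect_gt(abs(cor(res$evec, lab)), 0.95)

  # chi2 invariant to individual reordering (up to numerical noise)
  perm <- sample(nrow(g$geno$dosages))
  g2 <- genotype_matrix(g$geno$dosages[perm, ], g$geno$positions,
                        pop_labels = g$geno$pop_labels[perm])
  res2 <- eigengwas_scan(g2)
  expect_equal(res2$chi2, res$chi2, tolerance = 1e-6)
  expect_equal(res2$lambda_gc, res$lambda_gc, tolerance = 1e-8)

  # perfect-separator SNP attains the maximum chi2 when structure defines
  # the leading axis
  dos <- g$geno$dosages
  dos[, 400] <- ifelse(g$geno$pop_labels == "pop1", 2L, 0L)
  g3 <- genotype_matrix(dos, g$geno$positions,
                        pop_labels = g$geno$pop_labels)
  res3 <- eigengwas_scan(g3)
  expect_equal(which.max(res3$chi2), which(res3$keep == 400))

  expect_error(eigengwas_scan(genotype_matrix(matrix(c(0L, 1L), 1, 2), 1:2)),
               "2 individuals")
})

test_that("smooth_track reproduces constants and lines and finds a step", {
  tr <- scan_track(seq(0, 1e6, 5e4), rep(3, 21), statistic = "c")
  expect_equal(smooth_track(tr)$smoothed, rep(3, 21), tolerance = 1e-9)

  lin <- scan_track(seq(0, 1e6, 5e4), seq(0, 2, 0.1), statistic = "l")
  expect_equal(smooth_track(lin)$smoothed, lin$raw, tolerance = 1e-9)

  # noisy step: smoothed mean inside the elevated 1.6 Mb region > outside
  set.seed(29)
  pos <- seq(0, 5e6, 2e4)
  raw <- rnorm(length(pos), 1, 0.3) +
    ifelse(pos >= 1.7e6 & pos < 3.3e6, 1, 0)
  st <- smooth_track(scan_track(pos, raw, statistic = "s"))
  inside <- pos >= 1.7e6 & pos < 3.3e6
  expect_gt(mean(st$smoothed[inside]), mean(st$smoothed[!inside]))

  # kernel smoother, same property
  sk <- smooth_track(scan_track(pos, raw, statistic = "s"),
                     method = "kernel", bandwidth = 2e5)
  expect_gt(mean(sk$smoothed[inside]), mean(sk$smoothed[!inside]))

  expect_error(smooth_track(scan_track(1:5, rep(NA_real_, 5))), "no non-missing")
})
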