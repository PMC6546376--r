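make_series <- function(years, means, n = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(years), function(i)
    data.frame(id = "x", year = years[i],
               bill_mm = rnorm(n, means[i], sd),
               tarsus_mm = rnorm(n, 19, 0.5),
               sex = "F", site = "s")))
}

test_that("annual summaries match hand arithmetic and handle n = 1", {
  d <- data.frame(year = c(2000, 2000, 2001),
                  bill_mm = c(10, 12, 11), tarsus_mm = c(19, 20, 19))
  s <- annual_summaries(d, "bill")
  expect_equal(s$mean, c(11, 11))
  expect_equal(s$se[1], 1)          # sd = sqrt(2), se = sqrt(2)/sqrt(2)
  expect_equal(s$se[2], 0)          # single record
  expect_true(s$single[2])
  expect_error(annual_summaries(d[, 1:2], "tarsus"), "tarsus")
})

test_that("welch_t_test matches the direct formula and handles degeneracy", {
  # worked example: x = 1:3 vs y = 4:6
  r <- welch_t_test(1:3, 4:6)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4.0, tolerance = 1e-12)

  # identical samples
  r0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # brute-force agreement on random small samples
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), 0.5)
    o <- oracle_welch(x, y)
    r <- welch_t_test(x, y)
    expect_equal(r$t, o$t, tolerance = 1e-12)
    expect_equal(r$df, o$df, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }

  # zero variance in both groups
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p, 1)
  dz <- welch_t_test(c(1, 1), c(2, 2))
  expect_equal(dz$p, 0)
  expect_true(dz$degenerate)
})

test_that("breakpoint per-cut statistics match a brute-force oracle", {
  d <- make_series(2000:2011, c(rep(10, 6), rep(10.6, 6)), n = 8, seed = 5)
  bp <- max_sel_breakpoint(d, "bill", n_perm = 0)
  o <- oracle_cut_stats(d$year, d$bill_mm)
  expect_equal(bp$per_cut$stat, o$stat, tolerance = 1e-12)
  expect_equal(bp$per_cut$eligible, o$eligible)
  expect_equal(bp$best_cut, c(2005, 2006))
  expect_equal(bp$maxT, max(abs(o$stat[o$eligible])), tolerance = 1e-12)
})

test_that("maxT is invariant to shifting and scaling the trait", {
  d <- make_series(2000:2014, rnorm(15, 12, 0.4), n = 6, seed = 8)
  b0 <- max_sel_breakpoint(d, "bill", n_perm = 0)
  d2 <- d; d2$bill_mm <- 5 * d$bill_mm + 100
  b2 <- max_sel_breakpoint(d2, "bill", n_perm = 0)
  expect_equal(b2$maxT, b0$maxT, tolerance = 1e-10)
  expect_equal(b2$best_cut, b0$best_cut)
})

test_that("constant series gives maxT 0, p 1; permutation p is valid", {
  d <- make_series(2000:2011, rep(10, 12), n = 5, sd = 0)
  bp <- max_sel_breakpoint(d, "bill", n_perm = 100, seed = 1)
  expect_equal(bp$maxT, 0)
  expect_equal(bp$p, 1)

  # a strong injected step is recovered and significant
  d2 <- make_series(2000:2019, c(rep(10, 10), rep(11, 10)), n = 20,
                    sd = 0.4, seed = 2)
  bp2 <- max_sel_breakpoint(d2, "bill", n_perm = 500, seed = 3)
  expect_equal(bp2$best_cut, c(2009, 2010))
  expect_lt(bp2$p, 0.01)
})

test_that("fit_linear_trend recovers exact trends and the partial F", {
  # noise-free linear trait: slope exact, residual SS ~ 0
  yrs <- 2000:2009
  d <- data.frame(year = rep(yrs, each = 3),
                  bill_mm = 10 + 0.01 * rep(yrs - 2000, each = 3),
                  tarsus_mm = 19)
  f <- fit_linear_trend(d, "bill")
  expect_equal(f$slope, 0.01, tolerance = 1e-12)
  expect_lt(sum(residuals(f$fit)^2), 1e-20)

  # partial F against an explicit two-model SS ratio on a toy table
  d2 <- data.frame(year = c(2000, 2000, 2001, 2001, 2002, 2002),
                   bill_mm = c(10.1, 10.3, 10.0, 10.6, 10.9, 10.7),
                   tarsus_mm = c(19, 20, 19.5, 19, 20, 19.2))
  f2 <- fit_linear_trend(d2, "bill")
  rss1 <- sum(lm(bill_mm ~ year, d2)$residuals^2)
  rss0 <- sum((d2$bill_mm - mean(d2$bill_mm))^2)
  expect_equal(f2$F, (rss0 - rss1) / (rss1 / 4), tolerance = 1e-10)
  # with the covariate: F for dropping year from year + tarsus
  f3 <- fit_linear_trend(d2, "bill", covariate = "tarsus")
  rssf <- sum(lm(bill_mm ~ year + tarsus_mm, d2)$residuals^2)
  rssr <- sum(lm(bill_mm ~ tarsus_mm, d2)$residuals^2)
  expect_equal(f3$F, (rssr - rssf) / (rssf / 3), tolerance = 1e-10)
  expect_error(fit_linear_trend(d2[d2$year < 2002, ], "bill"), "3 distinct")
})

test_that("trend with a constant covariate equals the unadjusted trend", {
  d <- make_series(2000:2009, rnorm(10, 12, 0.2), n = 5, seed = 6)
  d$tarsus_mm <- 19
  f1 <- fit_linear_trend(d, "bill")
  f2 <- fit_linear_trend(d, "bill", covariate = "tarsus")
  expect_identical(f2$slope, f1$slope)
  expect_identical(f2$F, f1$F)
  expect_true(f2$covariate_dropped)
})

test_that("slope_scan enumerates the closed-form window count", {
  d <- make_series(1982:2007, rep(13, 26), n = 2, sd = 0.1)
  sc <- slope_scan(d, "bill", 10, 25)
  expect_equal(nrow(sc$windows), 152)       # sum over l of (27 - l)

  # closed form for random bounds
  for (i in 1:5) {
    set.seed(i)
    K <- sample(12:30, 1)
    lo <- sample(3:8, 1); hi <- sample(9:28, 1)
    d2 <- make_series(seq_len(K) + 1980, rep(10, K), n = 2, sd = 0.1,
                      seed = i)
    sc2 <- slope_scan(d2, "bill", lo, hi)
    lens <- lo:min(hi, K)
    expect_equal(nrow(sc2$windows), sum(K - lens + 1))
  }

  # strictly increasing series: every slope positive
  d3 <- data.frame(year = rep(1982:2007, each = 2),
                   bill_mm = rep(seq(10, 12.5, by = 0.1), each = 2),
                   tarsus_mm = 19)
  sc3 <- slope_scan(d3, "bill")
  expect_equal(nrow(sc3$windows), 152)
  expect_true(all(sc3$windows$slope > 0))
})

test_that("slope scan separates windows with and without the early plateau", {
  cfg <- pheno_sim_config(step_bill = 0.4, slope_bill = -0.01,
                          bill_sd = 0.3, seed = 14)
  ph <- generate_phenotypes(cfg)
  sc <- slope_scan(ph, "bill", early_years = 1982:1986)
  w <- sc$windows
  expect_gte(mean(w$slope[w$contains_early_years] > 0), 0.8)
  expect_gte(mean(w$slope[!w$contains_early_years] < 0), 0.8)
})

test_that("loess_smooth reproduces lines and matches stats::loess", {
  x <- seq(0, 1, length.out = 12)
  line <- 2 + 3 * x
  expect_equal(loess_smooth(x, line, degree = 1), line, tolerance = 1e-10)
  expect_equal(loess_smooth(x, line, degree = 2), line, tolerance = 1e-10)

  set.seed(10)
  x <- sort(runif(25)); y <- sin(5 * x) + rnorm(25, 0, 0.1)
  for (sp in c(0.4, 0.75, 1)) for (dg in 1:2) {
    ref <- fitted(loess(y ~ x, span = sp, degree = dg,
                        surface = "direct", family = "gaussian"))
    expect_equal(loess_smooth(x, y, span = sp, degree = dg), unname(ref),
                 tolerance = 1e-8)
  }
  expect_error(loess_smooth(x, y, span = 0.05), "span too small")
})

test_that("two-way ANOVA with Tukey letters matches hand sums of squares", {
  set.seed(12)
  d <- data.frame(
    site = rep(c("uk", "nl", "fr"), each = 20),
    sex = rep(rep(c("F", "M"), each = 10), 3),
    tarsus_mm = 19)
  d$bill_mm <- c(rnorm(20, 14.0, 0.2), rnorm(20, 13.4, 0.2),
                 rnorm(20, 13.4, 0.2))
  r <- anova_tukey(d, "bill", c("site", "sex"))
  # hand-computed sequential SS for the balanced design
  grand <- mean(d$bill_mm)
  ss_site <- sum(tapply(d$bill_mm, d$site, function(v)
    length(v) * (mean(v) - grand)^2))
  ms_res <- sum(aov(bill_mm ~ site + sex, d)$residuals^2) / (60 - 4)
  expect_equal(r$anova$F[r$anova$factor == "site"], (ss_site / 2) / ms_res,
               tolerance = 1e-10)
  expect_lt(r$anova$p[1], 0.001)    # site separates
  expect_gt(r$anova$p[2], 0.05)     # sex does not
  # uk alone in its letter group; nl and fr share one
  lt <- r$letters$site
  expect_false(lt["uk"] %in% lt[c("nl", "fr")])
  expect_equal(lt["nl"], lt["fr"], ignore_attr = TRUE)

  # identical value sets in two groups -> F = 0 for that factor
  d2 <- data.frame(site = rep(c("a", "b"), each = 4),
                   sex = rep(c("F", "M"), 4),
                   bill_mm = rep(c(10, 11, 12, 13), 2), tarsus_mm = 19)
  r2 <- anova_tukey(d2, "bill", c("site", "sex"))
  expect_equal(r2$anova$F[1], 0, tolerance = 1e-10)
})
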