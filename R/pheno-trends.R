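# Time-scale-sensitive analysis of an individual-level phenotype series:
# breakpoint detection by a maximally-selected standardized two-sample
# statistic, trend fits with/without an allometric covariate, exhaustive
# consecutive-year slope scans, LOESS smoothing, and two-way ANOVA with
# Tukey HSD.

# resolve a trait name to a numeric vector of per-record values
trait_values <- function(data, trait = c("bill", "tarsus", "ratio")) {
  trait <- match.arg(trait)
  need <- switch(trait, bill = "bill_mm", tarsus = "tarsus_mm",
                 ratio = c("bill_mm", "tarsus_mm"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("trait '", trait, "' needs missing column(s): ",
         paste(miss, collapse = ", "))
  switch(trait,
         bill = data$bill_mm,
         tarsus = data$tarsus_mm,
         ratio = data$bill_mm / data$tarsus_mm)
}

#' Annual means and standard errors
#'
#' Per-year mean and standard error (sd/sqrt(n)) of a trait over individual
#' records. Years with a single record get `se = 0` and are flagged.
#'
#' @param data phenotype data.frame (columns `year`, `bill_mm`, `tarsus_mm`).
#' @param trait `"bill"`, `"tarsus"` or `"ratio"` (per-individual
#'   bill/tarsus).
#' @return A data.frame with columns `year`, `n`, `mean`, `se`, `single`
#'   (TRUE where n = 1), ordered by year.
#' @export
annual_summaries <- function(data, trait = c("bill", "tarsus", "ratio")) {
  y <- trait_values(data, trait)
  yrs <- sort(unique(data$year))
  out <- do.call(rbind, lapply(yrs, function(yr) {
    v <- y[data$year == yr]
    n <- length(v)
    data.frame(year = yr, n = n, mean = mean(v),
               se = if (n > 1) stats::sd(v) / sqrt(n) else 0,
               single = n == 1)
  }))
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (fractional)
#' degrees of freedom and a two-sided p-value. Degenerate inputs are handled
#' explicitly: two constant samples with equal means give t = 0, p = 1; with
#' unequal means, p = 0 and the result is flagged degenerate.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return A list of class `welch_t` with elements `t`, `df`, `p`,
#'   `estimate` (the two means) and `degenerate`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_test needs at least two observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p = if (eq) 1 else 0,
                estimate = c(mean(x), mean(y)), degenerate = TRUE)
    return(structure(res, class = "welch_t"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, estimate = unname(tt$estimate),
                 degenerate = FALSE),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.4g, p = %.4g%s\n", x$t, x$df,
              x$p, if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

# standardized two-sample linear statistic for every eligible year-boundary
# cut. Standardization uses the exact permutation moments of the left-side
# sum: E[S] = n_L * ybar, Var[S] = n_L (N - n_L) / (N - 1) * mean((y-ybar)^2),
# so the statistic is invariant to shifting and scaling of the trait.
cut_statistics <- function(year, y, minprop, maxprop) {
  o <- order(year)
  year <- year[o]; y <- y[o]
  N <- length(y)
  yrs <- sort(unique(year))
  if (length(yrs) < 2) stop("need at least two distinct years")
  n_year <- tabulate(match(year, yrs))
  n_left <- cumsum(n_year)[-length(yrs)]          # left count per boundary
  eligible <- n_left >= minprop * N & n_left <= maxprop * N
  if (sum(eligible) < 2)
    stop("fewer than 2 eligible cutpoints under minprop/maxprop")
  ybar <- mean(y)
  v <- mean((y - ybar)^2)
  cs <- cumsum(y)
  S <- cs[n_left]
  E <- n_left * ybar
  V <- n_left * (N - n_left) / (N - 1) * v
  Tstat <- rep(NA_real_, length(n_left))
  if (v > 0) Tstat <- (S - E) / sqrt(V) else Tstat[] <- 0
  list(left_year = yrs[-length(yrs)], right_year = yrs[-1],
       n_left = n_left, stat = Tstat, eligible = eligible,
       y_sorted = y, N = N, ybar = ybar, v = v)
}

#' Maximally selected breakpoint in a phenotype series
#'
#' Scans every between-year boundary of an individual-level series for the
#' largest absolute standardized two-sample mean-difference statistic
#' (before vs after the cut), and assesses the maximum (maxT) against a
#' permutation null in which trait values are shuffled across individuals.
#' Candidate cuts must leave at least `minprop` and at most `maxprop` of
#' observations on the left; records within a year are never split.
#'
#' @param data phenotype data.frame.
#' @param trait `"bill"`, `"tarsus"` or `"ratio"`.
#' @param minprop,maxprop eligibility bounds on the left-side observation
#'   fraction (defaults 0.1 / 0.9).
#' @param n_perm permutations for the p-value (default 10000); 0 skips the
#'   permutation test (`p = NA`). The reported p uses the add-one correction
#'   (1 + #\{perm maxT >= observed\}) / (n_perm + 1).
#' @param seed optional seed for the permutation draw.
#' @return A list of class `breakpoint_result`: `best_cut` (years flanking
#'   the boundary), `maxT`, `p`, `per_cut` (data.frame of per-boundary
#'   statistics), and `ties` (all boundaries attaining maxT; the earliest is
#'   reported as `best_cut`).
#' @export
max_sel_breakpoint <- function(data, trait = "bill", minprop = 0.1,
                               maxprop = 0.9, n_perm = 10000, seed = NULL) {
  y <- trait_values(data, trait)
  st <- cut_statistics(data$year, y, minprop, maxprop)
  per_cut <- data.frame(left_year = st$left_year, right_year = st$right_year,
                        n_left = st$n_left, stat = st$stat,
                        eligible = st$eligible)
  el <- which(st$eligible)
  absT <- abs(st$stat[el])
  maxT <- max(absT)
  ties <- el[absT == maxT]
  best <- ties[1]
  p <- NA_real_
  if (st$v == 0) {
    maxT <- 0
    p <- 1
  } else if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    y0 <- st$y_sorted - st$ybar
    N <- st$N
    idx <- st$n_left[el]
    sdv <- sqrt(idx * (N - idx) / (N - 1) * st$v)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      cs <- cumsum(y0[sample.int(N)])
      if (max(abs(cs[idx]) / sdv) >= maxT) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(best_cut = c(st$left_year[best], st$right_year[best]),
                 maxT = maxT, p = p, per_cut = per_cut,
                 ties = cbind(left_year = st$left_year[ties],
                              right_year = st$right_year[ties]),
                 n_perm = n_perm),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat(sprintf("Best cutpoint between %d and %d (maxT = %.4g, permutation p = %s)\n",
              x$best_cut[1], x$best_cut[2], x$maxT,
              if (is.na(x$p)) "not computed" else format(x$p, digits = 4)))
  if (nrow(x$ties) > 1) cat("  (", nrow(x$ties), "tied boundaries )\n")
  invisible(x)
}

#' Linear trend fit with partial F for the year term
#'
#' Ordinary least squares of a trait on calendar year over individual
#' records (optionally adding tarsus length as a covariate), restricted to a
#' year range. The reported F is the partial F for dropping the year term
#' from the fitted model, i.e. the model comparison with vs without year at
#' the same covariate set.
#'
#' @param data phenotype data.frame.
#' @param trait `"bill"`, `"tarsus"` or `"ratio"`.
#' @param start_year,end_year inclusive year range (defaults: full series).
#' @param covariate `NULL` or `"tarsus"`.
#' @param annual_means if TRUE, fit on per-year trait means instead of
#'   individual records (covariate not supported in this mode).
#' @return A list of class `trend_fit`: `slope` (mm/year), `F`, `p`,
#'   `df_num`, `df_den`, `covariate_used`, `n`, `years`, `fit` (the lm).
#' @export
fit_linear_trend <- function(data, trait = "bill", start_year = NULL,
                             end_year = NULL, covariate = NULL,
                             annual_means = FALSE) {
  if (is.null(start_year)) start_year <- min(data$year)
  if (is.null(end_year)) end_year <- max(data$year)
  d <- data[data$year >= start_year & data$year <= end_year, , drop = FALSE]
  if (length(unique(d$year)) < 3)
    stop("need at least 3 distinct years in range")
  y <- trait_values(d, trait)
  if (annual_means) {
    if (!is.null(covariate))
      stop("covariate not supported with annual_means = TRUE")
    agg <- annual_summaries(d, trait)
    df <- data.frame(y = agg$mean, year = agg$year)
    full <- stats::lm(y ~ year, data = df)
    red <- stats::lm(y ~ 1, data = df)
  } else if (!is.null(covariate)) {
    if (!identical(covariate, "tarsus"))
      stop("only 'tarsus' is supported as covariate")
    if (stats::var(d$tarsus_mm) == 0) {
      # constant covariate carries no information: identical to the
      # unadjusted fit, which is what we return (flagged)
      out <- fit_linear_trend(data, trait, start_year, end_year)
      out$covariate_dropped <- TRUE
      return(out)
    }
    df <- data.frame(y = y, year = d$year, tarsus = d$tarsus_mm)
    full <- stats::lm(y ~ year + tarsus, data = df)
    red <- stats::lm(y ~ tarsus, data = df)
  } else {
    df <- data.frame(y = y, year = d$year)
    full <- stats::lm(y ~ year, data = df)
    red <- stats::lm(y ~ 1, data = df)
  }
  if (any(is.na(stats::coef(full))))
    stop("degenerate (collinear) design")
  an <- stats::anova(red, full)
  structure(list(slope = unname(stats::coef(full)["year"]),
                 F = an$F[2], p = an$`Pr(>F)`[2],
                 df_num = an$Df[2], df_den = an$Res.Df[2],
                 covariate_used = !is.null(covariate),
                 annual_means = annual_means,
                 n = nrow(df), years = c(start_year, end_year), fit = full),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend %d-%d%s: slope = %.5g mm/yr, F(%d,%d) = %.4g, p = %.3g\n",
              x$years[1], x$years[2],
              if (x$covariate_used) " (tarsus-adjusted)" else "",
              x$slope, x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

#' Exhaustive consecutive-year slope scan
#'
#' Fits one OLS slope of the trait on year for every window of consecutive
#' observed years whose length lies in `[min_len, max_len]`, and labels each
#' window by whether it contains any of the configured "early" years. This
#' makes visible how strongly the inferred trend depends on the analysed
#' time window.
#'
#' @param data phenotype data.frame.
#' @param trait `"bill"`, `"tarsus"` or `"ratio"`.
#' @param min_len,max_len window length bounds in years (defaults 10 / 25).
#' @param early_years years whose inclusion is flagged (default 1982:1986).
#' @return A list of class `slope_scan_result` with `windows`: a data.frame
#'   (start_year, end_year, length, slope, n, contains_early_years).
#' @export
slope_scan <- function(data, trait = "bill", min_len = 10, max_len = 25,
                       early_years = 1982:1986) {
  yrs <- sort(unique(data$year))
  K <- length(yrs)
  if (K <= min_len) stop("series has too few years for min_len")
  y <- trait_values(data, trait)
  rows <- list()
  for (len in seq(min_len, min(max_len, K))) {
    for (s in seq_len(K - len + 1)) {
      win <- yrs[s:(s + len - 1)]
      sel <- data$year %in% win
      yy <- y[sel]; xx <- data$year[sel]
      if (!length(yy)) next
      slope <- stats::cov(xx, yy) / stats::var(xx)
      rows[[length(rows) + 1]] <-
        data.frame(start_year = win[1], end_year = win[len], length = len,
                   slope = slope, n = length(yy),
                   contains_early_years = any(win %in% early_years))
    }
  }
  structure(list(windows = do.call(rbind, rows),
                 min_len = min_len, max_len = max_len,
                 early_years = early_years),
            class = "slope_scan_result")
}

#' @export
print.slope_scan_result <- function(x, ...) {
  w <- x$windows
  cat(sprintf("Slope scan: %d windows (lengths %d-%d); %d contain early years\n",
              nrow(w), x$min_len, x$max_len, sum(w$contains_early_years)))
  cat(sprintf("  slope sign: %d positive / %d negative\n",
              sum(w$slope > 0), sum(w$slope < 0)))
  invisible(x)
}

#' Tricube-weighted local polynomial (LOESS) smoother
#'
#' Local regression evaluated at the observed abscissae: at each x0 the q =
#' floor(span * n) nearest points get tricube weights
#' (1 - (d/h)^3)^3 with h the q-th nearest distance, and a degree-`degree`
#' weighted polynomial is fitted; the fitted value at x0 is returned. This
#' is the smoothing primitive used by all track smoothing in the package.
#'
#' @param x,y numeric vectors of equal length.
#' @param span fraction of points in the local neighbourhood, in (0, 1].
#' @param degree local polynomial degree (1 or 2).
#' @return Numeric vector of fitted values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 2) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (n < degree + 2) stop("need at least degree + 2 points")
  q <- floor(n * span + 1e-9)
  if (q < degree + 1) stop("span too small for a local degree-", degree, " fit")
  vapply(x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    w <- if (h > 0) (1 - pmin(d / h, 1)^3)^3 else as.numeric(d == 0)
    X <- outer(x - x0, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y, w)
    unname(fit$coefficients[1])
  }, 0.0)
}

#' Two-way additive ANOVA with Tukey HSD letters
#'
#' Fits `trait ~ factor1 + factor2` over individual records, reports the
#' per-factor F tests, and computes Tukey honest significant differences
#' with a compact letter display per factor (groups sharing a letter are not
#' significantly different at `alpha`).
#'
#' @param data phenotype data.frame.
#' @param trait `"bill"`, `"tarsus"` or `"ratio"`.
#' @param factors character vector of two column names (e.g. site/country
#'   and sex).
#' @param alpha significance level for the letter display (default 0.05).
#' @return A list of class `anova_tukey_result`: `anova` (data.frame of
#'   factor, df, F, p), `tukey` (named list of TukeyHSD tables), `letters`
#'   (named list of letter assignments per factor level).
#' @export
anova_tukey <- function(data, trait = "bill", factors = c("site", "sex"),
                        alpha = 0.05) {
  stopifnot(length(factors) == 2)
  miss <- setdiff(factors, names(data))
  if (length(miss)) stop("missing factor column(s): ", paste(miss, collapse = ", "))
  y <- trait_values(data, trait)
  f1 <- factor(data[[factors[1]]])
  f2 <- factor(data[[factors[2]]])
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("each factor needs at least 2 non-empty levels")
  df <- data.frame(y = y, f1 = f1, f2 = f2)
  fit <- stats::aov(y ~ f1 + f2, data = df)
  sm <- summary(fit)[[1]]
  an <- data.frame(factor = factors,
                   df = sm$Df[1:2], F = sm$`F value`[1:2],
                   p = sm$`Pr(>F)`[1:2])
  tk <- stats::TukeyHSD(fit)
  names(tk) <- factors
  letters <- list(
    cld_letters(tk[[1]], levels(f1), alpha),
    cld_letters(tk[[2]], levels(f2), alpha))
  names(letters) <- factors
  structure(list(anova = an, tukey = tk, letters = letters, fit = fit),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat("Two-way additive ANOVA:\n")
  print(x$anova, row.names = FALSE)
  for (f in names(x$letters)) {
    cat(sprintf("  %s letters: %s\n", f,
                paste(sprintf("%s=%s", names(x$letters[[f]]),
                              x$letters[[f]]), collapse = " ")))
  }
  invisible(x)
}

# compact letter display from a TukeyHSD table: maximal cliques of the
# "not significantly different at alpha" graph, one letter per clique.
cld_letters <- function(tukey_tab, lev, alpha = 0.05) {
  k <- length(lev)
  adj <- matrix(TRUE, k, k, dimnames = list(lev, lev))
  pairs <- rownames(tukey_tab)
  for (i in seq_along(pairs)) {
    ab <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    # level names may themselves contain '-': split at every position and
    # keep the one where both halves are valid levels
    for (cut in seq_len(length(ab) - 1)) {
      a <- paste(ab[1:cut], collapse = "-")
      b <- paste(ab[-(1:cut)], collapse = "-")
      if (a %in% lev && b %in% lev) {
        sig <- tukey_tab[i, "p adj"] < alpha
        adj[a, b] <- adj[b, a] <- !sig
        break
      }
    }
  }
  cliques <- max_cliques(adj)
  # stable letter order: cliques sorted by their first member's level order
  cliques <- cliques[order(vapply(cliques, min, 0L))]
  out <- setNames(rep("", k), lev)
  for (ci in seq_along(cliques)) {
    for (m in cliques[[ci]])
      out[m] <- paste0(out[m], LETTERS[ci])
  }
  out
}

# Bron-Kerbosch maximal cliques on a small undirected graph given as a
# logical adjacency matrix (diagonal TRUE)
max_cliques <- function(adj) {
  n <- nrow(adj)
  res <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      res[[length(res) + 1]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  res
}
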