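# Genome-scan statistics over haplotype/genotype matrices: LD decay,
# long-distance LD tracks, per-SNP Hudson FST, eigenGWAS with genomic
# control, site EHH (EHHS) and its integral (iES), windowed nucleotide
# diversity, and along-genome smoothing. All coordinates are 0-based
# half-open bp; VCF 1-based conversion happens only at I/O.

# columns passing a minor-allele-frequency filter on a haplotype matrix
hap_maf_keep <- function(hap, maf) {
  p <- colMeans(hap$alleles)
  p >= maf & p <= 1 - maf & p > 0 & p < 1
}

#' Haplotype r-squared between two sites
#'
#' The classical phased-LD measure: r2 = D^2 / (pA(1-pA) pB(1-pB)) computed
#' from two-locus haplotype frequencies. Monomorphic sites give `NA`
#' (undefined, masked). For unphased input see [genotype_r2()].
#'
#' @param hap a [haplotype_matrix()].
#' @param i,j site (column) indices.
#' @return r2 in [0, 1], or NA if either site is monomorphic.
#' @export
pairwise_r2 <- function(hap, i, j) {
  a <- hap$alleles[, i]
  b <- hap$alleles[, j]
  n <- length(a)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(a * b)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Genotype-correlation r-squared (unphased dialect)
#'
#' Squared Pearson correlation between dosage vectors at two sites; the
#' standard substitute for haplotype r2 when phase is unavailable. Clearly
#' labeled as the unphased dialect in track metadata wherever used.
#'
#' @param geno a [genotype_matrix()].
#' @param i,j site indices.
#' @return Squared correlation, or NA if either site is constant.
#' @export
genotype_r2 <- function(geno, i, j) {
  a <- geno$dosages[, i]; b <- geno$dosages[, j]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# enumerate site pairs with separation in [min_sep, max_sep] and compute
# haplotype r2 for each, vectorized per left site
ld_pairs <- function(hap, min_sep, max_sep, maf = 0.05) {
  keep <- which(hap_maf_keep(hap, maf))
  pos <- hap$positions[keep]
  X <- hap$alleles[, keep, drop = FALSE]
  n <- nrow(X)
  m <- length(keep)
  p <- colMeans(X)
  out_i <- vector("list", m)
  for (ii in seq_len(m)) {
    lo <- findInterval(pos[ii] + min_sep - 0.5, pos) + 1
    hi <- findInterval(pos[ii] + max_sep + 0.5, pos)
    if (hi < lo) next
    js <- lo:hi
    pAB <- colMeans(X[, js, drop = FALSE] * X[, ii])
    D <- pAB - p[ii] * p[js]
    r2 <- D^2 / (p[ii] * (1 - p[ii]) * p[js] * (1 - p[js]))
    out_i[[ii]] <- data.frame(pos_a = pos[ii], pos_b = pos[js],
                              dist = pos[js] - pos[ii], r2 = r2)
  }
  out <- do.call(rbind, out_i)
  if (is.null(out))
    out <- data.frame(pos_a = numeric(0), pos_b = numeric(0),
                      dist = numeric(0), r2 = numeric(0))
  out
}

#' LD decay with distance
#'
#' Mean haplotype r2 per pair-distance bin (log-spaced by default), with a
#' LOESS-smoothed curve over the non-empty bins. Bins without eligible pairs
#' are reported as NA (empty), never as zero.
#'
#' @param hap a [haplotype_matrix()].
#' @param max_dist maximum pair separation in bp (default 50 kb).
#' @param n_bins number of distance bins.
#' @param log_bins log-spaced bin edges (default) or linear.
#' @param maf minor-allele-frequency filter (default 0.05).
#' @param span LOESS span for the smoothed curve.
#' @return A [scan_track()] over distance: positions are bin midpoints (bp),
#'   raw the per-bin mean r2; `meta` carries per-bin pair counts, bin edges
#'   and the estimator dialect.
#' @export
ld_decay_curve <- function(hap, max_dist = 50e3, n_bins = 20,
                           log_bins = TRUE, maf = 0.05, span = 0.75) {
  pr <- ld_pairs(hap, 1, max_dist, maf)
  if (nrow(pr) < 1) stop("no eligible site pairs after MAF filter")
  lo <- max(1, min(pr$dist))
  edges <- if (log_bins) exp(seq(log(lo), log(max_dist), length.out = n_bins + 1))
           else seq(lo, max_dist, length.out = n_bins + 1)
  edges[1] <- lo - 0.5
  bin <- cut(pr$dist, edges, labels = FALSE, include.lowest = TRUE)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mean_r2 <- rep(NA_real_, n_bins)
  n_pairs <- integer(n_bins)
  agg <- tapply(pr$r2, bin, mean)
  cnt <- tapply(pr$r2, bin, length)
  idx <- as.integer(names(agg))
  mean_r2[idx] <- agg
  n_pairs[idx] <- cnt
  ok <- !is.na(mean_r2)
  sm <- rep(NA_real_, n_bins)
  if (sum(ok) >= 4)
    sm[ok] <- tricube_predict(mids[ok], mean_r2[ok], mids[ok],
                              span = span, degree = 1)
  scan_track(mids, mean_r2, smoothed = sm, statistic = "ld_decay",
             chrom = hap$chrom,
             meta = list(n_pairs = n_pairs, edges = edges,
                         dialect = "haplotype_r2", maf = maf))
}

#' Long-distance LD track along the chromosome
#'
#' Per window, the mean haplotype r2 over all site pairs whose midpoint
#' falls in the window and whose separation lies in `[min_sep, max_sep]`
#' (defaults 20-200 kb: the "long distance" LD of a coldspot scan). Windows
#' without eligible pairs are NA.
#'
#' @param hap a [haplotype_matrix()].
#' @param window,step window size and step in bp (defaults 200 kb / 50 kb).
#' @param min_sep,max_sep pair-separation bounds in bp.
#' @param maf minor-allele-frequency filter.
#' @return A [scan_track()] with positions at window midpoints.
#' @export
long_distance_ld_track <- function(hap, window = 200e3, step = 50e3,
                                   min_sep = 20e3, max_sep = 200e3,
                                   maf = 0.05) {
  pr <- ld_pairs(hap, min_sep, max_sep, maf)
  L <- hap$chrom_length
  starts <- seq(0, max(0, L - 1), by = step)
  starts <- starts[starts < L]
  ends <- pmin(starts + window, L)
  mid_pair <- (pr$pos_a + pr$pos_b) / 2
  raw <- rep(NA_real_, length(starts))
  nps <- integer(length(starts))
  for (w in seq_along(starts)) {
    inw <- mid_pair >= starts[w] & mid_pair < starts[w] + window
    nps[w] <- sum(inw)
    if (nps[w] > 0) raw[w] <- mean(pr$r2[inw])
  }
  scan_track((starts + ends) / 2, raw, statistic = "r2_longdist",
             chrom = hap$chrom,
             window = list(size = window, step = step),
             meta = list(min_sep = min_sep, max_sep = max_sep,
                         n_pairs = nps, dialect = "haplotype_r2", maf = maf))
}

#' Per-SNP Hudson FST
#'
#' The Hudson/Bhatia per-SNP estimator:
#' numerator (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1), denominator
#' p1(1-p2) + p2(1-p1), with n the number of called allele copies per
#' population. Raw values are reported (slightly negative values are the
#' finite-sample behaviour under no differentiation, not an error). Sites
#' monomorphic in both populations, or with fewer than 2 called alleles in
#' either, are masked.
#'
#' @param geno a [genotype_matrix()] with two populations in `pop_labels`,
#'   or with `pops` naming two of its labels.
#' @param pops optional character vector of the two labels to contrast.
#' @return A [scan_track()] of per-SNP FST at site positions.
#' @export
hudson_fst_per_snp <- function(geno, pops = NULL) {
  if (is.null(geno$pop_labels)) stop("genotype matrix has no pop_labels")
  if (is.null(pops)) pops <- unique(geno$pop_labels)
  if (length(pops) != 2) stop("exactly two populations are required")
  d1 <- geno$dosages[geno$pop_labels == pops[1], , drop = FALSE]
  d2 <- geno$dosages[geno$pop_labels == pops[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / n1
  p2 <- colSums(d2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- num / den
  mono_both <- (p1 %in% c(0, 1)) & (p2 == p1)
  fst[mono_both | n1 < 2 | n2 < 2] <- NA_real_
  scan_track(geno$positions, fst, statistic = "fst", chrom = geno$chrom,
             meta = list(estimator = "hudson_bhatia", pops = pops))
}

#' eigenGWAS scan
#'
#' Association of each SNP with the leading eigenvector of the
#' individual-by-individual genotype covariance (the axis of population
#' structure). Dosages are standardized by mean 2p and sd sqrt(2p(1-p));
#' missing dosages are mean-imputed for this computation. The per-SNP 1-df
#' chi-square is the score statistic n * cor(SNP, eigenvector)^2; inflation
#' is summarized by the median-based genomic-control factor
#' lambda_GC = median(chi2)/0.4549 and corrected p-values use
#' chi2/lambda_GC. Both raw and GC-corrected p are returned.
#'
#' Note that with an in-sample leading eigenvector, lambda_GC exceeds 1 even
#' in a single panmictic population whenever the SNP/individual ratio is
#' modest (the top sampling eigenvalue of the standardized covariance is
#' (1+sqrt(n/m))^2 > 1); the GC-corrected p-values are the calibrated
#' output.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of leading eigenvectors (only k = 1 is supported).
#' @param maf minor-allele-frequency filter (default 0.05).
#' @return An object of class `eigengwas_result`: `positions`, `chi2`,
#'   `p_raw`, `p_gc`, `lambda_gc`, `evec` (per-individual scores),
#'   `evalues` (leading eigenvalues), `keep` (indices of SNPs used).
#' @export
eigengwas_scan <- function(geno, k = 1, maf = 0.05) {
  if (k != 1) stop("only k = 1 is supported")
  X <- geno$dosages
  if (nrow(X) < 2) stop("need at least 2 individuals")
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- which(p >= maf & p <= 1 - maf)
  if (length(keep) < 2) stop("fewer than 2 SNPs pass the MAF filter")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(X)
  m <- ncol(X)
  Xs <- scale(X, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
  Xs[is.na(Xs)] <- 0          # mean imputation in standardized units
  K <- tcrossprod(Xs) / m
  ev <- eigen(K, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (stats::sd(v1) == 0) stop("leading eigenvector is constant")
  r <- as.vector(stats::cor(Xs, v1))
  chi2 <- n * r^2
  lambda <- stats::median(chi2) / stats::qchisq(0.5, 1)
  structure(list(positions = geno$positions[keep], chi2 = chi2,
                 p_raw = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 p_gc = stats::pchisq(chi2 / lambda, 1, lower.tail = FALSE),
                 lambda_gc = lambda, evec = v1,
                 evalues = ev$values[seq_len(min(10, n))],
                 keep = keep, chrom = geno$chrom, n = n, m = m),
            class = "eigengwas_result")
}

#' @export
print.eigengwas_result <- function(x, ...) {
  cat(sprintf("eigenGWAS: %d SNPs x %d individuals, lambda_GC = %.3f, top eigenvalue %.2f\n",
              x$m, x$n, x$lambda_gc, x$evalues[1]))
  invisible(x)
}

#' Convert an eigenGWAS result to a -log10(p) scan track
#'
#' @param x an `eigengwas_result`.
#' @param corrected use GC-corrected p (default) or raw p.
#' @return A [scan_track()] of -log10 p at SNP positions.
#' @export
eigengwas_track <- function(x, corrected = TRUE) {
  p <- if (corrected) x$p_gc else x$p_raw
  scan_track(x$positions, -log10(p),
             statistic = if (corrected) "eigengwas_mlog10p_gc"
                         else "eigengwas_mlog10p_raw",
             chrom = x$chrom,
             meta = list(lambda_gc = x$lambda_gc, corrected = corrected))
}

#' Site extended haplotype homozygosity (EHHS) curve
#'
#' For a focal site, EHHS at position x is the probability that two
#' haplotypes drawn without replacement are identical at every site strictly
#' between the focal site and x (x included, focal excluded), computed by
#' prefix grouping outward in both directions. By convention EHHS at the
#' focal site itself (distance 0) is 1; the curve is non-increasing with
#' distance.
#'
#' @param hap a phased [haplotype_matrix()].
#' @param focal focal site (column index); must be polymorphic.
#' @return A data.frame with columns `position`, `dist` (signed bp from the
#'   focal site) and `ehhs`, ordered by position.
#' @export
ehhs_curve <- function(hap, focal) {
  a <- hap$alleles
  n <- nrow(a)
  m <- ncol(a)
  pf <- mean(a[, focal])
  if (pf %in% c(0, 1)) stop("focal site must be polymorphic")
  npairs <- n * (n - 1) / 2
  walk <- function(idx) {
    g <- integer(n)                  # one group: identical over empty interval
    vals <- numeric(length(idx))
    for (t in seq_along(idx)) {
      g2 <- g * 2L + a[, idx[t]]
      counts <- tabulate(g2 + 1L)
      vals[t] <- sum(counts * (counts - 1)) / 2 / npairs
      ids <- which(counts > 0L)
      g <- match(g2 + 1L, ids) - 1L
      if (vals[t] == 0) {            # all groups singletons: stays 0
        if (t < length(idx)) vals[(t + 1):length(idx)] <- 0
        break
      }
    }
    vals
  }
  right_idx <- if (focal < m) (focal + 1):m else integer(0)
  left_idx <- if (focal > 1) (focal - 1):1 else integer(0)
  pos <- hap$positions
  out <- data.frame(
    position = c(rev(pos[left_idx]), pos[focal], pos[right_idx]),
    ehhs = c(rev(walk(left_idx)), 1, walk(right_idx)))
  out$dist <- out$position - pos[focal]
  out[, c("position", "dist", "ehhs")]
}

#' Integrated EHHS (iES) scan
#'
#' For every focal site, integrates the EHHS curve over bp by the trapezoid
#' rule in both directions, truncating once EHHS drops below `truncation`
#' (the first sub-threshold point still contributes its trapezoid) or at the
#' chromosome ends, where the outermost EHHS value is extended to the
#' boundary. Reported per Mb, so a chromosome whose haplotypes never
#' differentiate away from the focal site scores its full length in Mb.
#'
#' @param hap a phased [haplotype_matrix()].
#' @param truncation EHHS truncation threshold (default 0.05).
#' @return A [scan_track()] of iES (Mb) at site positions; monomorphic focal
#'   sites are masked.
#' @export
ies_scan <- function(hap, truncation = 0.05) {
  a <- hap$alleles
  n <- nrow(a)
  m <- ncol(a)
  pos <- hap$positions
  L <- hap$chrom_length
  npairs <- n * (n - 1) / 2
  p <- colMeans(a)
  ies <- rep(NA_real_, m)
  for (f in seq_len(m)) {
    if (p[f] %in% c(0, 1)) next
    total <- 0
    for (dirn in c(1L, -1L)) {
      idx <- if (dirn == 1L) {
        if (f < m) (f + 1):m else integer(0)
      } else {
        if (f > 1) (f - 1):1 else integer(0)
      }
      prev_val <- 1
      prev_pos <- pos[f]
      g <- integer(n)
      truncated <- FALSE
      for (t in idx) {
        g2 <- g * 2L + a[, t]
        counts <- tabulate(g2 + 1L)
        val <- sum(counts * (counts - 1)) / 2 / npairs
        total <- total + (prev_val + val) / 2 * abs(pos[t] - prev_pos)
        prev_val <- val
        prev_pos <- pos[t]
        if (val < truncation) { truncated <- TRUE; break }
        ids <- which(counts > 0L)
        g <- match(g2 + 1L, ids) - 1L
      }
      if (!truncated) {   # extend outermost value to the chromosome end
        edge <- if (dirn == 1L) L else 0
        total <- total + prev_val * abs(edge - prev_pos)
      }
    }
    ies[f] <- total / 1e6
  }
  if (m < 2) ies[] <- NA_real_
  scan_track(pos, ies, statistic = "iES", chrom = hap$chrom,
             meta = list(truncation = truncation, unit = "Mb"))
}

#' Windowed nucleotide diversity
#'
#' Per window, pi = (sum over sites of pairwise differences) / (n choose 2)
#' / window length, counting monomorphic positions as zero diversity (no MAF
#' filter is applied). Windows are 0-based half-open `[start, start+window)`
#' from position 0; a final window truncated by the chromosome end uses its
#' own length as denominator.
#'
#' @param hap a [haplotype_matrix()].
#' @param window window size in bp (default 200 kb).
#' @param step step in bp (default: non-overlapping, = window).
#' @return A [scan_track()] of per-bp pi at window midpoints.
#' @export
pi_windows <- function(hap, window = 200e3, step = window) {
  n <- nrow(hap$alleles)
  cnt <- colSums(hap$alleles)
  diffs <- cnt * (n - cnt)               # pairwise differences per site
  npairs <- n * (n - 1) / 2
  L <- hap$chrom_length
  starts <- seq(0, max(0, L - 1), by = step)
  starts <- starts[starts < L]
  ends <- pmin(starts + window, L)
  raw <- numeric(length(starts))
  ns <- integer(length(starts))
  for (w in seq_along(starts)) {
    inw <- hap$positions >= starts[w] & hap$positions < starts[w] + window
    ns[w] <- sum(inw)
    raw[w] <- sum(diffs[inw]) / npairs / (ends[w] - starts[w])
  }
  scan_track((starts + ends) / 2, raw, statistic = "pi", chrom = hap$chrom,
             window = list(size = window, step = step),
             meta = list(n_sites = ns))
}

#' Chromosome-wide nucleotide diversity
#'
#' @param hap a [haplotype_matrix()].
#' @return Mean pairwise difference per bp over the whole chromosome.
#' @export
pi_total <- function(hap) {
  n <- nrow(hap$alleles)
  cnt <- colSums(hap$alleles)
  sum(cnt * (n - cnt)) / (n * (n - 1) / 2) / hap$chrom_length
}

# tricube local-polynomial fit on (x, y), evaluated at x0 (shared engine of
# loess_smooth and smooth_track)
tricube_predict <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(n * span + 1e-9)
  q <- max(q, degree + 1)
  q <- min(q, n)
  vapply(x0, function(xx) {
    d <- abs(x - xx)
    h <- sort(d)[q]
    w <- if (h > 0) (1 - pmin(d / h, 1)^3)^3 else as.numeric(d == 0)
    X <- outer(x - xx, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y, w)
    unname(fit$coefficients[1])
  }, 0.0)
}

#' Smooth a scan track along the genome
#'
#' Position-ordered local regression (default; the same tricube engine as
#' [loess_smooth()]) or Gaussian-kernel smoothing of a track's raw values.
#' Masked (NA) positions are excluded from the fit but receive smoothed
#' values from the surrounding data.
#'
#' @param track a [scan_track()].
#' @param method `"loess"` or `"kernel"`.
#' @param span LOESS span; default chosen so the smoothing neighbourhood
#'   covers about 1 Mb of the track's extent.
#' @param bandwidth Gaussian kernel sd in bp (default 250 kb).
#' @param degree local polynomial degree for `"loess"`.
#' @return The track with its `smoothed` field filled on the same grid.
#' @export
smooth_track <- function(track, method = c("loess", "kernel"), span = NULL,
                         bandwidth = 250e3, degree = 2) {
  method <- match.arg(method)
  ok <- !is.na(track$raw)
  if (!any(ok)) stop("track has no non-missing values to smooth")
  x <- track$positions[ok]
  y <- track$raw[ok]
  if (method == "loess") {
    if (is.null(span)) {
      extent <- diff(range(track$positions))
      span <- if (extent > 0) min(1, 1e6 / extent) else 1
    }
    span <- max(span, min(1, (degree + 2) / length(x)))
    sm <- tricube_predict(x, y, track$positions, span = span, degree = degree)
  } else {
    sm <- vapply(track$positions, function(xx) {
      w <- stats::dnorm(x - xx, sd = bandwidth)
      sum(w * y) / sum(w)
    }, 0.0)
  }
  track$smoothed <- sm
  track$meta$smoother <- list(method = method,
                              span = if (method == "loess") span else NULL,
                              bandwidth = if (method == "kernel") bandwidth
                                          else NULL,
                              degree = degree)
  track
}
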