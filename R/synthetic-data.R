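#' Configuration for a synthetic bill/tarsus phenotype series
#'
#' Describes an individual-level, multi-year bivariate phenotype series
#' (bill length and tarsus length, mm) with optional step change and linear
#' drift. The defaults emulate a 26-year great tit monitoring series in which
#' the first five years sit on a lower level than the rest and the series
#' drifts slightly downward: the scenario in which a whole-series regression
#' and a post-step regression disagree in sign.
#'
#' @param years integer vector of calendar years, strictly increasing.
#' @param n_per_year number of measured individuals per year (>= 2).
#' @param bill_mean0,tarsus_mean0 baseline trait means (mm) in the first year.
#' @param bill_sd,tarsus_sd within-year standard deviations (mm).
#' @param rho bill-tarsus correlation within year, in [-1, 1].
#' @param step_year first year of the shifted level, or NULL for no step.
#' @param step_bill,step_tarsus level shift (mm) added from `step_year` onward.
#' @param slope_bill,slope_tarsus linear drift (mm/year) across the series.
#' @param seed integer seed; generation is fully deterministic given it.
#'
#' @details Within a year the pair (bill, tarsus) is bivariate normal with
#'   the configured year-specific means, standard deviations and correlation.
#'   The defaults (30 birds/year, sd 0.45/0.60 mm, rho 0.5, +0.25 mm step in
#'   year 6 of 26, -0.005 mm/yr drift) are the package's stated study
#'   conditions for end-to-end phenotype-pipeline validation.
#'
#' @return An object of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(years = 1982:2007, n_per_year = 30,
                             bill_mean0 = 13.2, tarsus_mean0 = 19.6,
                             bill_sd = 0.45, tarsus_sd = 0.6, rho = 0.5,
                             step_year = 1987, step_bill = 0.25,
                             step_tarsus = 0.35,
                             slope_bill = -0.005, slope_tarsus = -0.007,
                             seed = 1L) {
  years <- as.integer(years)
  if (length(years) < 1) stop("config error: years must be non-empty")
  if (length(years) > 1 && any(diff(years) <= 0))
    stop("config error: years must be strictly increasing")
  if (n_per_year < 2) stop("config error: n_per_year must be >= 2")
  if (!is.finite(rho) || abs(rho) > 1)
    stop("config error: rho must lie in [-1, 1]")
  if (bill_sd < 0 || tarsus_sd < 0) stop("config error: sds must be >= 0")
  if (!is.null(step_year)) step_year <- as.integer(step_year)
  structure(list(years = years, n_per_year = as.integer(n_per_year),
                 bill_mean0 = bill_mean0, tarsus_mean0 = tarsus_mean0,
                 bill_sd = bill_sd, tarsus_sd = tarsus_sd, rho = rho,
                 step_year = step_year, step_bill = step_bill,
                 step_tarsus = step_tarsus, slope_bill = slope_bill,
                 slope_tarsus = slope_tarsus, seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Generate an individual-level phenotype series
#'
#' Draws one record per bird-year from the bivariate normal model described
#' by the configuration: year mean = baseline + drift * (year - first year)
#' + step (from `step_year` onward), with the configured within-year sds and
#' bill-tarsus correlation.
#'
#' @param config a [pheno_sim_config()].
#' @return A data.frame with columns `id`, `year`, `bill_mm`, `tarsus_mm`,
#'   `sex` ("F"/"M"), `site`.
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  c0 <- config
  set.seed(c0$seed)
  y0 <- c0$years[1]
  out <- lapply(c0$years, function(yr) {
    n <- c0$n_per_year
    mb <- c0$bill_mean0 + c0$slope_bill * (yr - y0)
    mt <- c0$tarsus_mean0 + c0$slope_tarsus * (yr - y0)
    if (!is.null(c0$step_year) && yr >= c0$step_year) {
      mb <- mb + c0$step_bill
      mt <- mt + c0$step_tarsus
    }
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    bill <- mb + c0$bill_sd * z1
    tarsus <- mt + c0$tarsus_sd * (c0$rho * z1 + sqrt(1 - c0$rho^2) * z2)
    data.frame(year = yr, bill_mm = bill, tarsus_mm = tarsus,
               sex = sample(c("F", "M"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- sprintf("bird%05d", seq_len(nrow(out)))
  out$site <- "siteA"
  out[, c("id", "year", "bill_mm", "tarsus_mm", "sex", "site")]
}

#' Configuration for a two-population structured genotype panel
#'
#' Balding-Nichols-style divergence model: per-SNP subpopulation allele
#' frequencies are drawn from a beta distribution around an ancestral
#' frequency with dispersion set by the target FST, giving closed-form
#' control of expected differentiation. Optionally, a subset of SNPs gets an
#' extra +/- `delta_p` frequency shift in opposite directions (known
#' "divergent" loci for scan validation).
#'
#' @param n_per_pop diploid individuals per population (two populations).
#' @param n_snps number of SNPs.
#' @param fst_target target FST in [0, 1).
#' @param maf_range bounds of the uniform ancestral allele-frequency
#'   distribution.
#' @param n_divergent number of SNPs given the extra shift (<= n_snps).
#' @param delta_p frequency shift applied to divergent SNPs (+ in pop1,
#'   - in pop2), clipped into (0, 1).
#' @param spacing_bp mean inter-SNP spacing used to lay SNPs on a nominal
#'   chromosome (positions are only cosmetic for this panel).
#' @param seed integer seed.
#' @return An object of class `structured_pop_config`.
#' @export
structured_pop_config <- function(n_per_pop = 100, n_snps = 5000,
                                  fst_target = 0.1, maf_range = c(0.1, 0.9),
                                  n_divergent = 0, delta_p = 0.2,
                                  spacing_bp = 1000, seed = 1L) {
  if (fst_target < 0 || fst_target >= 1)
    stop("config error: fst_target must lie in [0, 1)")
  if (n_divergent > n_snps)
    stop("config error: n_divergent must be <= n_snps")
  if (n_per_pop < 2) stop("config error: n_per_pop must be >= 2")
  structure(list(n_pops = 2L, n_per_pop = as.integer(n_per_pop),
                 n_snps = as.integer(n_snps), fst_target = fst_target,
                 maf_range = maf_range, n_divergent = as.integer(n_divergent),
                 delta_p = delta_p, spacing_bp = spacing_bp,
                 seed = as.integer(seed)),
            class = "structured_pop_config")
}

#' Generate a structured two-population genotype panel
#'
#' @param config a [structured_pop_config()].
#' @return A list of class `structured_genotypes` with elements `geno`
#'   (a [genotype_matrix()] with `pop_labels` "pop1"/"pop2"), `divergent`
#'   (indices of the shifted SNPs), `p_anc`, `p_pop` (2 x n_snps matrix of
#'   realized subpopulation frequencies) and `config`.
#' @export
generate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "structured_pop_config"))
  c0 <- config
  set.seed(c0$seed)
  m <- c0$n_snps
  n <- c0$n_per_pop
  p_anc <- stats::runif(m, c0$maf_range[1], c0$maf_range[2])
  Fst <- c0$fst_target
  if (Fst > 0) {
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    p1 <- stats::rbeta(m, a, b)
    p2 <- stats::rbeta(m, a, b)
  } else {
    p1 <- p_anc
    p2 <- p_anc
  }
  divergent <- integer(0)
  if (c0$n_divergent > 0) {
    divergent <- sample.int(m, c0$n_divergent)
    eps <- 1e-4
    p1[divergent] <- pmin(pmax(p1[divergent] + c0$delta_p, eps), 1 - eps)
    p2[divergent] <- pmin(pmax(p2[divergent] - c0$delta_p, eps), 1 - eps)
  }
  g1 <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, p1[j]), integer(n))
  g2 <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, p2[j]), integer(n))
  dos <- rbind(g1, g2)
  positions <- cumsum(1 + stats::rgeom(m, 1 / c0$spacing_bp))
  geno <- genotype_matrix(dos, positions, chrom = "1",
                          pop_labels = rep(c("pop1", "pop2"), each = n))
  structure(list(geno = geno, divergent = sort(divergent), p_anc = p_anc,
                 p_pop = rbind(pop1 = p1, pop2 = p2), config = c0),
            class = "structured_genotypes")
}

#' Write / read a phenotype table as TSV
#'
#' Columns: id, year, bill_mm, tarsus_mm, sex, site.
#'
#' @param data a phenotype data.frame as from [generate_phenotypes()].
#' @param path file path.
#' @return `write_phenotypes_tsv` returns `path` invisibly;
#'   `read_phenotypes_tsv` returns the data.frame.
#' @export
write_phenotypes_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "year", "bill_mm", "tarsus_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Write a two-column population map TSV
#'
#' @param ids individual identifiers.
#' @param pops population labels, same length as `ids`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_popmap_tsv <- function(ids, pops, path) {
  stopifnot(length(ids) == length(pops))
  utils::write.table(data.frame(id = ids, pop = pops), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
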