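#' Piecewise-constant recombination map
#'
#' Ordered, non-overlapping, 0-based half-open intervals covering the whole
#' chromosome `[0, L)`, each with a per-bp per-generation crossover rate.
#'
#' @param starts,ends interval bounds in bp (half-open).
#' @param rates per-bp per-generation crossover rates (>= 0).
#' @param L chromosome length in bp.
#' @return An object of class `recombination_map` (data.frame-like list).
#' @export
recombination_map <- function(starts, ends, rates, L) {
  stopifnot(length(starts) == length(ends), length(ends) == length(rates))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; rates <- rates[o]
  if (any(rates < 0)) stop("rates must be >= 0")
  if (starts[1] != 0 || ends[length(ends)] != L ||
      (length(starts) > 1 && any(starts[-1] != ends[-length(ends)])))
    stop("intervals must tile [0, L) without gaps or overlaps")
  structure(list(start = starts, end = ends, rate = rates, L = L),
            class = "recombination_map")
}

#' Recombination map with a central coldspot
#'
#' Uniform base rate with one interval at `factor` times the base rate —
#' the "recombination coldspot" of a linked-selection experiment.
#'
#' @param L chromosome length bp.
#' @param base_rate per-bp per-generation rate outside the coldspot.
#' @param coldspot_start,coldspot_len coldspot location and length bp;
#'   default: centered, 8% of L (1.6 Mb on a 20 Mb chromosome).
#' @param factor rate multiplier inside the coldspot (default 0.01).
#' @return A [recombination_map()] with attribute `coldspot = c(start, end)`.
#' @export
coldspot_map <- function(L = 20e6, base_rate = 1e-8,
                         coldspot_start = NULL, coldspot_len = 0.08 * L,
                         factor = 0.01) {
  if (is.null(coldspot_start)) coldspot_start <- (L - coldspot_len) / 2
  cs <- coldspot_start
  ce <- coldspot_start + coldspot_len
  stopifnot(cs > 0, ce < L)
  m <- recombination_map(c(0, cs, ce), c(cs, ce, L),
                         c(base_rate, base_rate * factor, base_rate), L)
  attr(m, "coldspot") <- c(cs, ce)
  m
}

#' Distribution of fitness effects for new mutations
#'
#' A fraction `p_deleterious` of new mutations is deleterious with selection
#' coefficient `s` (fixed, or gamma-distributed magnitude with mean `|s|`
#' and shape `s_shape`) and dominance `h`; the rest are strictly neutral.
#' No beneficial mutations exist in this model.
#'
#' @param p_deleterious fraction of new mutations that are deleterious.
#' @param s selection coefficient of the deleterious class (negative).
#' @param h dominance coefficient of deleterious mutations.
#' @param s_shape NULL for fixed s, or a gamma shape for a distributed |s|.
#' @return An object of class `dfe_config`.
#' @export
dfe_config <- function(p_deleterious = 0.3, s = -0.02, h = 0.25,
                       s_shape = NULL) {
  if (p_deleterious < 0 || p_deleterious > 1)
    stop("p_deleterious must lie in [0, 1]")
  if (p_deleterious > 0 && s >= 0)
    stop("s must be negative for the deleterious class")
  structure(list(p_deleterious = p_deleterious, s = s, h = h,
                 s_shape = s_shape),
            class = "dfe_config")
}

#' Forward-simulation parameter set
#'
#' @param N diploid population size (>= 2).
#' @param L chromosome length bp.
#' @param mu per-bp per-generation mutation rate.
#' @param map a [recombination_map()] covering `[0, L)`.
#' @param dfe a [dfe_config()].
#' @param burnin generations to run (default 10 N).
#' @param sample_n haplotypes sampled at the end (<= 2N).
#' @param seed integer seed (NULL: use the current RNG state).
#' @param rescale_Q bookkeeping record of any rescaling applied.
#' @return An object of class `forward_sim_params`.
#' @export
forward_sim_params <- function(N = 5000, L = 20e6, mu = 1e-8,
                               map = coldspot_map(L), dfe = dfe_config(),
                               burnin = 10 * N, sample_n = 100,
                               seed = NULL, rescale_Q = 1) {
  if (N < 2) stop("N must be >= 2")
  if (L < 1) stop("L must be >= 1")
  if (mu < 0) stop("mu must be >= 0")
  if (sample_n > 2 * N) stop("sample_n must be <= 2N")
  if (map$L != L) stop("map length does not match L")
  structure(list(N = as.integer(N), L = L, mu = mu, map = map, dfe = dfe,
                 burnin = as.integer(burnin), sample_n = as.integer(sample_n),
                 seed = seed, rescale_Q = rescale_Q),
            class = "forward_sim_params")
}

#' Rescale a parameter set for desk-scale runs
#'
#' Standard population-size rescaling by a factor Q: N -> N/Q, mu -> mu*Q,
#' all map rates -> rate*Q, s -> s*Q, burn-in -> 10 N/Q, preserving the
#' products N*mu, N*r and N*s.
#'
#' @param params a [forward_sim_params()].
#' @param Q rescaling factor (>= 1, N/Q >= 2).
#' @return The rescaled parameter set.
#' @export
rescale_params <- function(params, Q) {
  stopifnot(inherits(params, "forward_sim_params"))
  if (Q < 1) stop("Q must be >= 1")
  N2 <- params$N / Q
  if (N2 < 2) stop("N/Q must be >= 2")
  s2 <- params$dfe$s * Q
  if (params$dfe$p_deleterious > 0 && s2 <= -1)
    stop("rescaled s*Q <= -1: fitness would be non-positive")
  map <- params$map
  map$rate <- map$rate * Q
  dfe <- params$dfe
  dfe$s <- s2
  forward_sim_params(N = round(N2), L = params$L, mu = params$mu * Q,
                     map = map, dfe = dfe, burnin = round(10 * N2),
                     sample_n = min(params$sample_n, 2 * round(N2)),
                     seed = params$seed,
                     rescale_Q = params$rescale_Q * Q)
}

#' Desk-scale coldspot preset
#'
#' The package's desk-scale realization of the coldspot experiment: a 5 Mb
#' chromosome with a central 400 kb coldspot at 1% of the base crossover
#' rate, N = 5000, mu = r = 1e-8 per bp, deleterious fraction 0.3 with
#' gamma-free fixed s and h = 0.25, rescaled by Q = 10 (so N = 500, 5000
#' burn-in generations, products N mu, N r, N s preserved).
#'
#' @param seed integer seed.
#' @param p_deleterious deleterious fraction (set 0 for the neutral control).
#' @param s,h selection and dominance coefficients (unscaled).
#' @param Q rescaling factor.
#' @param sample_n haplotypes sampled at the end.
#' @return A rescaled [forward_sim_params()] whose map carries the coldspot
#'   attribute.
#' @export
desk_scale_params <- function(seed = 1L, p_deleterious = 0.3, s = -0.02,
                              h = 0.25, Q = 10, sample_n = 100) {
  L <- 5e6
  base <- forward_sim_params(
    N = 5000, L = L, mu = 1e-8,
    map = coldspot_map(L, base_rate = 1e-8, coldspot_len = 400e3,
                       factor = 0.01),
    dfe = dfe_config(p_deleterious = p_deleterious, s = s, h = h),
    burnin = 50000, sample_n = sample_n, seed = seed)
  rescale_params(base, Q)
}

#' Simulate one crossover product (gamete) of two haplotypes
#'
#' Crossover counts per map interval are Poisson(rate x interval length),
#' breakpoint locations uniform within the interval; the gamete alternates
#' parental origin at the sorted breakpoints, starting from either parent
#' with probability 1/2.
#'
#' @param hap_a,hap_b parental allele vectors on the same positions grid.
#' @param positions bp position per allele.
#' @param map a [recombination_map()].
#' @return A list: `gamete` (allele vector), `breakpoints` (bp, sorted),
#'   `start_parent` ("a" or "b").
#' @export
recombine_gamete <- function(hap_a, hap_b, positions, map) {
  stopifnot(length(hap_a) == length(hap_b),
            length(hap_a) == length(positions))
  lens <- map$end - map$start
  cnts <- stats::rpois(length(lens), map$rate * lens)
  bks <- sort(unlist(lapply(seq_along(cnts), function(k) {
    if (cnts[k] == 0) return(numeric(0))
    stats::runif(cnts[k], map$start[k], map$end[k])
  })))
  from_a <- stats::runif(1) < 0.5
  seg <- findInterval(positions, bks)       # 0,1,2,... segment index
  use_a <- (seg %% 2 == 0) == from_a
  list(gamete = ifelse(use_a, hap_a, hap_b), breakpoints = bks,
       start_parent = if (from_a) "a" else "b")
}

#' Read a simulator configuration from YAML or JSON
#'
#' The file mirrors the parameter set: top-level `N`, `L`, `mu`, `burnin`,
#' `sample_n`, `seed`, optional `rescale_Q` (applied via
#' [rescale_params()]), a `dfe` block (`p_deleterious`, `s`, `h`, optional
#' `s_shape`), and either a `map` block with parallel `start`/`end`/`rate`
#' arrays or a `coldspot` block (`start`, `length`, `factor`, optional
#' `base_rate`).
#'
#' @param path path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return A [forward_sim_params()], rescaled if `rescale_Q` was given.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    y <- yaml::read_yaml(path)
    # YAML 1.1 quirks: a bare `N` key is read as boolean FALSE, and
    # exponent notation without a sign ("5.0e6") as a string; normalize
    names(y)[names(y) == "FALSE"] <- "N"
    rapply(y, function(v) {
      if (is.character(v) && length(v) == 1 &&
          grepl("^-?[0-9.]+e[+-]?[0-9]+$", v, ignore.case = TRUE))
        as.numeric(v) else v
    }, how = "replace")
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (f in c("N", "L", "mu")) if (is.null(cfg[[f]]))
    stop("simulator config is missing field: ", f)
  map <- if (!is.null(cfg$coldspot)) {
    coldspot_map(cfg$L,
                 base_rate = cfg$coldspot$base_rate %||% 1e-8,
                 coldspot_start = cfg$coldspot$start,
                 coldspot_len = cfg$coldspot$length,
                 factor = cfg$coldspot$factor %||% 0.01)
  } else if (!is.null(cfg$map)) {
    recombination_map(cfg$map$start, cfg$map$end, cfg$map$rate, cfg$L)
  } else stop("simulator config needs a 'map' or 'coldspot' block")
  dfe <- do.call(dfe_config, as.list(cfg$dfe %||% list()))
  params <- forward_sim_params(
    N = cfg$N, L = cfg$L, mu = cfg$mu, map = map, dfe = dfe,
    burnin = cfg$burnin %||% (10 * cfg$N),
    sample_n = cfg$sample_n %||% 100, seed = cfg$seed)
  if (!is.null(cfg$rescale_Q) && cfg$rescale_Q != 1)
    params <- rescale_params(params, cfg$rescale_Q)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a forward Wright-Fisher simulation
#'
#' Discrete non-overlapping generations: parents are drawn with probability
#' proportional to multiplicative fitness across deleterious sites
#' (heterozygote 1 + h s, homozygote 1 + s, s <= 0); each gamete receives
#' Poisson(mu L) new mutations at uniform integer bp (collisions re-drawn);
#' fixed mutations are pruned into a substitution log so diversity
#' statistics are unaffected; after `burnin` generations, `sample_n`
#' haplotypes are drawn without replacement. Fully deterministic given
#' `params$seed`.
#'
#' @param params a [forward_sim_params()].
#' @param init_mutations optional data.frame (position, count, s) of
#'   standing variants present at generation 0 (validation harness for
#'   drift/fixation checks).
#' @return An object of class `sim_sample`: `hap` (a [haplotype_matrix()]),
#'   `mutations` (position, s, origin per segregating site in the sample),
#'   `substitutions`, `params`.
#' @export
run_simulation <- function(params, init_mutations = NULL) {
  stopifnot(inherits(params, "forward_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(init_mutations))
    init_mutations <- data.frame(position = integer(0), count = integer(0),
                                 s = numeric(0))
  dfe <- params$dfe
  res <- .cpp_run_simulation(
    params$N, params$L, params$mu,
    params$map$start, params$map$end, params$map$rate,
    dfe$p_deleterious, dfe$s,
    if (is.null(dfe$s_shape)) -1 else dfe$s_shape,
    dfe$h, params$burnin, params$sample_n,
    as.integer(init_mutations$position), as.integer(init_mutations$count),
    as.numeric(init_mutations$s))
  hap <- haplotype_matrix(res$alleles, res$positions, chrom = "1",
                          chrom_length = params$L)
  structure(list(
    hap = hap,
    mutations = data.frame(position = res$positions, s = res$sel,
                           origin = res$origin),
    substitutions = data.frame(position = res$sub_positions,
                               s = res$sub_sel, origin = res$sub_origin,
                               fixed_gen = res$sub_gen),
    params = params),
    class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("<sim_sample> %d haplotypes, %d segregating sites (%d deleterious), %d substitutions\n",
              nrow(x$hap$alleles), ncol(x$hap$alleles),
              sum(x$mutations$s < 0), nrow(x$substitutions)))
  invisible(x)
}

#' Coldspot-versus-flanks contrast of scan tracks
#'
#' For each track, compares the mean statistic over positions inside the
#' coldspot with the mean over the flanks (positions at least `flank_margin`
#' bp away from the coldspot boundaries).
#'
#' @param tracks a [scan_track()] or named list of scan tracks.
#' @param coldspot numeric c(start, end), 0-based half-open bp.
#' @param flank_margin bp excluded on each side of the coldspot from the
#'   flank mean (buffer against smoothing bleed; default 0).
#' @param use `"raw"` or `"smoothed"` values.
#' @return A data.frame: statistic, inside_mean, outside_mean, ratio,
#'   n_inside, n_outside.
#' @export
coldspot_contrast <- function(tracks, coldspot, flank_margin = 0,
                              use = c("raw", "smoothed")) {
  use <- match.arg(use)
  if (inherits(tracks, "scan_track")) tracks <- list(tracks)
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, function(t) t$statistic, "")
  rows <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    v <- if (use == "smoothed") tr$smoothed else tr$raw
    if (is.null(v)) stop("track '", nm, "' has no ", use, " values")
    ins <- tr$positions >= coldspot[1] & tr$positions < coldspot[2]
    out <- tr$positions < coldspot[1] - flank_margin |
           tr$positions >= coldspot[2] + flank_margin
    if (!any(ins & !is.na(v)))
      stop("coldspot contains no scored position for track '", nm, "'")
    im <- mean(v[ins], na.rm = TRUE)
    om <- mean(v[out], na.rm = TRUE)
    data.frame(statistic = nm, inside_mean = im, outside_mean = om,
               ratio = im / om, n_inside = sum(ins & !is.na(v)),
               n_outside = sum(out & !is.na(v)))
  })
  do.call(rbind, rows)
}
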