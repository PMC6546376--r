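# Orchestration and I/O: VCF read/write, BED-like track export, run
# manifests, and the two end-to-end experiments (phenotype time-scale
# reanalysis; scaled coldspot/background-selection experiment).

#' Write a haplotype or genotype matrix as VCF
#'
#' Biallelic SNP records with a GT field on one chromosome; phased `a|b`
#' calls for haplotype matrices (consecutive haplotype pairs = individuals),
#' unphased `0/1`-style calls for genotype matrices (NA dosage becomes
#' `./.`). Internal 0-based positions are converted to 1-based VCF POS at
#' this boundary. Output is gzip-compressed (use a `.vcf.gz` path).
#'
#' @param x a [haplotype_matrix()] or [genotype_matrix()].
#' @param path output path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_matrix")) {
    sm <- x$sample_map
    if (is.null(sm)) stop("haplotype matrix has no individual pairing")
    ids <- sort(unique(sm))
    gt <- vapply(ids, function(i) {
      hp <- x$alleles[sm == i, , drop = FALSE]
      paste(hp[1, ], hp[2, ], sep = "|")
    }, character(ncol(x$alleles)))
    if (ncol(x$alleles) == 1) gt <- matrix(gt, nrow = 1)
    colnames(gt) <- sprintf("ind%03d", ids)
    positions <- x$positions
    chrom <- x$chrom
    clen <- x$chrom_length
  } else if (inherits(x, "genotype_matrix")) {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- apply(x$dosages, 1, function(row) {
      out <- code[as.character(row)]
      out[is.na(row)] <- "./."
      out
    })
    if (ncol(x$dosages) == 1) gt <- matrix(gt, nrow = 1)
    colnames(gt) <- sprintf("ind%03d", seq_len(nrow(x$dosages)))
    positions <- x$positions
    chrom <- x$chrom
    clen <- max(positions) + 1
  } else stop("x must be a haplotype_matrix or genotype_matrix")
  m <- length(positions)
  fix <- cbind(CHROM = rep(chrom, m),
               POS = format(positions + 1, scientific = FALSE, trim = TRUE),
               ID = rep(".", m), REF = rep("A", m), ALT = rep("T", m),
               QUAL = rep(".", m), FILTER = rep("PASS", m),
               INFO = rep(".", m))
  gt <- cbind(FORMAT = rep("GT", m), gt)
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(clen)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF into genotype (and, if phased, haplotype) matrices
#'
#' Single-chromosome biallelic SNPs; 1-based VCF POS becomes the internal
#' 0-based coordinate. Missing genotypes are preserved as NA dosages and
#' excluded from per-site allele counts downstream. Multi-allelic records
#' are skipped (with a message) or raise an error, per `multiallelic`.
#'
#' @param path VCF path (plain or gzipped).
#' @param region optional numeric c(start, end), 1-based inclusive VCF
#'   coordinates, to subset sites.
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @param pop_labels optional per-individual population labels, or a path to
#'   a two-column id/pop TSV.
#' @return A list: `geno` (a [genotype_matrix()]), `hap` (a
#'   [haplotype_matrix()] if all calls are phased, else NULL), `phased`,
#'   `samples`.
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "error"),
                     pop_labels = NULL) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                      # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF contains no records")
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1)
    stop("expected a single chromosome, found: ", paste(chroms, collapse = ","))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s); first at VCF line POS ",
           fix[which(multi)[1], "POS"])
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  pos1 <- as.numeric(fix[, "POS"])
  if (!is.null(region))
    keep <- keep & pos1 >= region[1] & pos1 <= region[2]
  gt <- v@gt[keep, -1, drop = FALSE]
  pos0 <- pos1[keep] - 1
  samples <- colnames(gt)
  fmt <- v@gt[keep, 1]
  gtfield <- vapply(strsplit(fmt, ":", fixed = TRUE),
                    function(f) which(f == "GT")[1], 0L)
  calls <- vapply(seq_len(nrow(gt)), function(i) {
    vapply(strsplit(gt[i, ], ":", fixed = TRUE),
           function(x) x[gtfield[i]], "")
  }, character(ncol(gt)))
  calls <- matrix(calls, nrow = ncol(gt))     # individuals x sites
  phased <- all(grepl("|", calls, fixed = TRUE) | calls %in% c(".", "./."))
  al1 <- substr(calls, 1, 1)
  al3 <- substr(calls, 3, 3)
  dos <- matrix(NA_integer_, nrow(calls), ncol(calls))
  ok <- al1 %in% c("0", "1") & al3 %in% c("0", "1")
  dos[ok] <- (al1 == "1")[ok] + (al3 == "1")[ok]
  if (is.character(pop_labels) && length(pop_labels) == 1 &&
      file.exists(pop_labels)) {
    pm <- utils::read.delim(pop_labels, stringsAsFactors = FALSE)
    pop_labels <- pm$pop[match(samples, pm$id)]
  }
  geno <- genotype_matrix(dos, pos0, chrom = chroms, pop_labels = pop_labels)
  hap <- NULL
  if (phased && !anyNA(dos)) {
    alle <- matrix(0L, 2 * nrow(calls), ncol(calls))
    alle[seq(1, 2 * nrow(calls), 2), ] <- as.integer(al1 == "1")
    alle[seq(2, 2 * nrow(calls), 2), ] <- as.integer(al3 == "1")
    hap <- haplotype_matrix(alle, pos0, chrom = chroms)
  }
  list(geno = geno, hap = hap, phased = phased, samples = samples)
}

#' Write a scan track as a BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), statistic, raw, smoothed.
#' Windowed tracks export their window bounds; per-site tracks export
#' single-bp intervals.
#'
#' @param track a [scan_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  if (!is.null(track$window)) {
    half <- track$window$size / 2
    start <- pmax(0, track$positions - half)
    end <- track$positions + half
  } else {
    start <- track$positions
    end <- track$positions + 1
  }
  d <- data.frame(chrom = track$chrom, start = start, end = end,
                  statistic = track$statistic, raw = track$raw,
                  smoothed = if (is.null(track$smoothed)) NA
                             else track$smoothed)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run manifest written alongside every pipeline output bundle
write_manifest <- function(out_dir, config, master_seed, stage_seeds,
                           inputs = character(0)) {
  digests <- if (length(inputs))
    vapply(inputs, function(f) as.character(tools::md5sum(f)), "")
    else NULL
  man <- list(tool = "evoscan",
              version = as.character(utils::packageVersion("evoscan")),
              master_seed = master_seed, stage_seeds = stage_seeds,
              config = config, input_digests = digests,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(man)
}

#' End-to-end phenotype time-scale reanalysis
#'
#' Runs the full phenotype battery on an individual-level series: annual
#' summaries, maximally selected breakpoint, Welch t-test of the records
#' before vs after the best cut, linear trends (trait with and without
#' tarsus covariate, tarsus, bill/tarsus ratio; full range and post-cut
#' range), the exhaustive consecutive-year slope scan, and a LOESS fit to
#' the annual means. Optionally writes TSV/JSON reports plus a manifest.
#'
#' @param pheno a phenotype data.frame or path to a phenotype TSV.
#' @param trait primary trait (default "bill").
#' @param n_perm permutations for the breakpoint test.
#' @param seed master seed (stage seeds are derived from it).
#' @param min_len,max_len,early_years passed to [slope_scan()]; early_years
#'   defaults to the first five observed years.
#' @param loess_span span of the LOESS fit to annual means.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return A list of class `pheno_report` with elements `summaries`,
#'   `breakpoint`, `welch_pre_post`, `trends`, `slopes`, `loess`, `config`.
#' @export
run_pheno_reanalysis <- function(pheno, trait = "bill", n_perm = 10000,
                                 seed = 1L, min_len = 10, max_len = 25,
                                 early_years = NULL, loess_span = 0.75,
                                 out_dir = NULL) {
  pheno_path <- NULL
  if (is.character(pheno)) {
    pheno_path <- pheno
    pheno <- read_phenotypes_tsv(pheno)
  }
  need <- c("year", "bill_mm", "tarsus_mm")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "))
  yrs <- sort(unique(pheno$year))
  if (is.null(early_years)) early_years <- yrs[seq_len(min(5, length(yrs)))]

  summaries <- lapply(c(bill = "bill", tarsus = "tarsus", ratio = "ratio"),
                      function(tr) annual_summaries(pheno, tr))
  bp <- max_sel_breakpoint(pheno, trait, n_perm = n_perm,
                           seed = derive_seed(seed, 1))
  v <- trait_values(pheno, trait)
  pre <- v[pheno$year <= bp$best_cut[1]]
  post <- v[pheno$year >= bp$best_cut[2]]
  welch <- welch_t_test(pre, post)

  post_start <- bp$best_cut[2]
  trends <- list(
    full = fit_linear_trend(pheno, trait),
    post = fit_linear_trend(pheno, trait, start_year = post_start),
    post_tarsus_adj = if (trait == "bill")
      fit_linear_trend(pheno, trait, start_year = post_start,
                       covariate = "tarsus") else NULL,
    tarsus_full = fit_linear_trend(pheno, "tarsus"),
    tarsus_post = fit_linear_trend(pheno, "tarsus", start_year = post_start),
    ratio_full = fit_linear_trend(pheno, "ratio"),
    ratio_post = fit_linear_trend(pheno, "ratio", start_year = post_start))
  trends <- trends[!vapply(trends, is.null, TRUE)]

  slopes <- slope_scan(pheno, trait, min_len = min_len, max_len = max_len,
                       early_years = early_years)
  ann <- summaries[[trait]]
  lo <- data.frame(year = ann$year,
                   fitted = loess_smooth(ann$year, ann$mean,
                                         span = loess_span))
  config <- list(trait = trait, n_perm = n_perm, min_len = min_len,
                 max_len = max_len, early_years = early_years,
                 loess_span = loess_span)

  res <- structure(list(summaries = summaries, breakpoint = bp,
                        welch_pre_post = welch, trends = trends,
                        slopes = slopes, loess = lo, config = config),
                   class = "pheno_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tr in names(summaries))
      utils::write.table(summaries[[tr]],
                         file.path(out_dir, paste0("annual_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bp$per_cut, file.path(out_dir, "breakpoint_cuts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(slopes$windows,
                       file.path(out_dir, "slope_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lo, file.path(out_dir, "loess_annual.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trend_tab <- do.call(rbind, lapply(names(trends), function(nm) {
      t <- trends[[nm]]
      data.frame(model = nm, start = t$years[1], end = t$years[2],
                 slope = t$slope, F = t$F, p = t$p,
                 df_num = t$df_num, df_den = t$df_den,
                 tarsus_covariate = t$covariate_used)
    }))
    utils::write.table(trend_tab, file.path(out_dir, "trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(best_cut = bp$best_cut, maxT = bp$maxT, p = bp$p,
           welch = list(t = welch$t, df = welch$df, p = welch$p),
           trends = lapply(trends, function(t)
             list(slope = t$slope, F = t$F, p = t$p)),
           n_windows = nrow(slopes$windows)),
      file.path(out_dir, "pheno_summary.json"),
      auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, config, seed,
                   list(breakpoint = derive_seed(seed, 1)),
                   inputs = if (is.null(pheno_path)) character(0)
                            else pheno_path)
  }
  res
}

#' @export
print.pheno_report <- function(x, ...) {
  print(x$breakpoint)
  print(x$welch_pre_post)
  for (nm in names(x$trends)) {
    cat(sprintf("%-16s", nm)); print(x$trends[[nm]])
  }
  print(x$slopes)
  invisible(x)
}

# compute the four coldspot-experiment tracks for one simulated sample
replicate_tracks <- function(sim, pi_window = 200e3, ld_window = 200e3,
                             ld_step = 50e3, maf = 0.05) {
  hap <- sim$hap
  geno <- hap_to_geno(hap)
  eg <- eigengwas_scan(geno, maf = maf)
  list(
    pi = pi_windows(hap, window = pi_window),
    r2_longdist = long_distance_ld_track(hap, window = ld_window,
                                         step = ld_step, maf = maf),
    iES = ies_scan(hap),
    eigengwas = smooth_track(eigengwas_track(eg)),
    lambda_gc = eg$lambda_gc)
}

#' Scaled coldspot / background-selection experiment
#'
#' For each replicate: run the forward simulation, compute windowed
#' nucleotide diversity, the long-distance (20-200 kb) LD track, the iES
#' scan and the smoothed eigenGWAS -log10 p track, then contrast the
#' coldspot against the flanks. Replicates use seeds derived from the master
#' seed; a failing replicate is recorded and the run continues. The expected
#' pattern with deleterious mutations on: lower pi, higher long-distance r2,
#' higher iES and higher eigenGWAS significance inside the coldspot.
#'
#' @param params a [forward_sim_params()] whose map has a coldspot attribute
#'   (default: [desk_scale_params()]).
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param flank_margin bp excluded around the coldspot from the flank means.
#' @param out_dir optional output directory (per-replicate track TSVs and a
#'   manifest are written there).
#' @return A list of class `coldspot_report`: `contrasts` (per-replicate
#'   data.frames), `summary` (per-statistic count of replicates in the
#'   expected direction), `pi_ratios`, `failed`, `params`.
#' @export
run_coldspot_experiment <- function(params = desk_scale_params(),
                                    n_replicates = 10, seed = 1L,
                                    flank_margin = 100e3, out_dir = NULL) {
  coldspot <- attr(params$map, "coldspot")
  if (is.null(coldspot)) stop("params$map has no coldspot attribute")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contrasts <- vector("list", n_replicates)
  lambda <- rep(NA_real_, n_replicates)
  failed <- logical(n_replicates)
  stage_seeds <- vapply(seq_len(n_replicates),
                        function(r) derive_seed(seed, r), 0.0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      p <- params
      p$seed <- stage_seeds[r]
      sim <- run_simulation(p)
      tr <- replicate_tracks(sim)
      lambda[r] <- tr$lambda_gc
      tracks <- tr[c("pi", "r2_longdist", "iES")]
      con <- rbind(
        coldspot_contrast(tracks, coldspot, flank_margin, use = "raw"),
        coldspot_contrast(list(eigengwas = tr$eigengwas), coldspot,
                          flank_margin, use = "smoothed"))
      if (!is.null(out_dir)) {
        rep_dir <- file.path(out_dir, sprintf("replicate%02d", r))
        dir.create(rep_dir, showWarnings = FALSE)
        for (nm in names(tracks))
          write_track_tsv(tracks[[nm]],
                          file.path(rep_dir, paste0(nm, ".tsv")))
        write_track_tsv(tr$eigengwas,
                        file.path(rep_dir, "eigengwas.tsv"))
      }
      con
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed[r] <- TRUE else contrasts[[r]] <- res
  }
  okc <- contrasts[!failed]
  direction <- c(pi = "below", r2_longdist = "above", iES = "above",
                 eigengwas = "above")
  summary <- do.call(rbind, lapply(names(direction), function(st) {
    ratios <- vapply(okc, function(cc) cc$ratio[cc$statistic == st], 0.0)
    hits <- if (direction[[st]] == "below") sum(ratios < 1)
            else sum(ratios > 1)
    data.frame(statistic = st, direction = direction[[st]],
               n_expected_direction = hits, n_replicates = length(ratios),
               mean_ratio = mean(ratios))
  }))
  pi_ratios <- vapply(okc, function(cc) cc$ratio[cc$statistic == "pi"], 0.0)
  out <- structure(list(contrasts = contrasts, summary = summary,
                        pi_ratios = pi_ratios, lambda_gc = lambda,
                        failed = failed, coldspot = coldspot,
                        params = params),
                   class = "coldspot_report")
  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "contrast_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir,
                   list(N = params$N, L = params$L, mu = params$mu,
                        dfe = unclass(params$dfe), burnin = params$burnin,
                        sample_n = params$sample_n,
                        rescale_Q = params$rescale_Q,
                        coldspot = coldspot,
                        flank_margin = flank_margin,
                        n_replicates = n_replicates),
                   seed, as.list(stage_seeds))
  }
  out
}

#' @export
print.coldspot_report <- function(x, ...) {
  cat(sprintf("Coldspot experiment: %d replicates (%d failed), coldspot %g-%g bp\n",
              length(x$contrasts), sum(x$failed), x$coldspot[1],
              x$coldspot[2]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
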