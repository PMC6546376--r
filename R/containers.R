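#' Phased haplotype matrix
#'
#' The substrate of all haplotype-based genome scans: a binary matrix of
#' alleles (rows = haplotypes, columns = segregating sites) together with
#' 0-based, strictly increasing base-pair positions on a single chromosome.
#'
#' @param alleles integer or numeric matrix of 0/1 alleles, one row per
#'   haplotype, one column per site.
#' @param positions numeric vector of 0-based bp positions, strictly
#'   increasing, one per column of `alleles`.
#' @param chrom chromosome identifier (single string).
#' @param chrom_length total chromosome length in bp; defaults to just past
#'   the last site. Used as the integration/window bound by scan statistics.
#' @param sample_map optional integer vector mapping each haplotype row to a
#'   diploid individual (1-based); defaults to consecutive pairing when the
#'   number of haplotypes is even.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `alleles`, `positions`, `chrom`, `chrom_length`, `sample_map`.
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "1",
                             chrom_length = NULL, sample_map = NULL) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1")
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles))
    stop("length(positions) must equal ncol(alleles)")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing (no duplicates)")
  if (any(positions < 0))
    stop("positions are 0-based and must be >= 0")
  if (is.null(chrom_length))
    chrom_length <- if (length(positions)) max(positions) + 1 else 1
  if (length(positions) && chrom_length <= max(positions))
    stop("chrom_length must exceed the last position")
  n_hap <- nrow(alleles)
  if (is.null(sample_map) && n_hap %% 2 == 0)
    sample_map <- rep(seq_len(n_hap / 2), each = 2)
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1],
                 chrom_length = as.numeric(chrom_length),
                 sample_map = sample_map),
            class = "haplotype_matrix")
}

#' Diploid genotype dosage matrix
#'
#' Rows are individuals, columns are sites; entries are counts of the
#' alternate allele in {0, 1, 2} or `NA` for missing calls.
#'
#' @param dosages numeric/integer matrix of dosages (0, 1, 2, or NA).
#' @param positions 0-based bp positions, strictly increasing.
#' @param chrom chromosome identifier.
#' @param pop_labels optional character/factor vector of population labels,
#'   one per individual (row).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, positions, chrom = "1",
                            pop_labels = NULL) {
  dosages <- as.matrix(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  positions <- as.numeric(positions)
  if (length(positions) != ncol(dosages))
    stop("length(positions) must equal ncol(dosages)")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (!is.null(pop_labels)) {
    if (length(pop_labels) != nrow(dosages))
      stop("pop_labels must cover all individuals")
    pop_labels <- as.character(pop_labels)
  }
  structure(list(dosages = dosages, positions = positions,
                 chrom = as.character(chrom)[1], pop_labels = pop_labels),
            class = "genotype_matrix")
}

#' Collapse a phased haplotype matrix to diploid dosages
#'
#' Consecutive haplotype pairs (or the matrix's `sample_map`) are summed into
#' per-individual alternate-allele dosages.
#'
#' @param hap a [haplotype_matrix()].
#' @param pop_labels optional per-individual population labels.
#' @return A [genotype_matrix()].
#' @export
hap_to_geno <- function(hap, pop_labels = NULL) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  sm <- hap$sample_map
  if (is.null(sm)) stop("haplotype matrix has no individual pairing")
  ids <- sort(unique(sm))
  dos <- t(vapply(ids, function(i) colSums(hap$alleles[sm == i, , drop = FALSE]),
                  numeric(ncol(hap$alleles))))
  genotype_matrix(dos, hap$positions, hap$chrom, pop_labels)
}

#' Per-position scan track
#'
#' A genome scan result: one raw (and optionally smoothed) value per position
#' or per window midpoint, for a named statistic.
#'
#' @param positions bp coordinates (site positions or window midpoints).
#' @param raw raw statistic values (may contain NA for masked positions).
#' @param smoothed optional smoothed values on the same grid.
#' @param statistic name of the statistic (e.g. "pi", "iES", "r2_longdist").
#' @param chrom chromosome identifier.
#' @param window optional list(size, step) in bp for windowed statistics.
#' @param meta optional named list of method metadata (estimator dialect,
#'   filters applied, ...), carried into output files.
#' @return An object of class `scan_track`.
#' @export
scan_track <- function(positions, raw, smoothed = NULL, statistic = "stat",
                       chrom = "1", window = NULL, meta = list()) {
  positions <- as.numeric(positions)
  raw <- as.numeric(raw)
  if (length(positions) != length(raw))
    stop("positions and raw must have the same length")
  if (!is.null(smoothed) && length(smoothed) != length(raw))
    stop("smoothed must be on the same grid as raw")
  structure(list(positions = positions, raw = raw,
                 smoothed = if (is.null(smoothed)) NULL else as.numeric(smoothed),
                 statistic = statistic, chrom = as.character(chrom)[1],
                 window = window, meta = meta),
            class = "scan_track")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d sites, chrom %s, length %s bp\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom,
              format(x$chrom_length, big.mark = ",")))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites, chrom %s%s\n",
              nrow(x$dosages), ncol(x$dosages), x$chrom,
              if (is.null(x$pop_labels)) "" else
                sprintf(", pops: %s", paste(unique(x$pop_labels), collapse = "/"))))
  invisible(x)
}

#' @export
print.scan_track <- function(x, ...) {
  cat(sprintf("<scan_track> %s: %d positions on chrom %s (%d masked)%s\n",
              x$statistic, length(x$positions), x$chrom, sum(is.na(x$raw)),
              if (is.null(x$smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' Convert a scan track to a data frame
#'
#' @param x a [scan_track()].
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return A data.frame with columns chrom, position, raw and (if present)
#'   smoothed.
#' @export
as.data.frame.scan_track <- function(x, row.names = NULL, optional = FALSE, ...) {
  d <- data.frame(chrom = x$chrom, position = x$positions, raw = x$raw,
                  stringsAsFactors = FALSE)
  if (!is.null(x$smoothed)) d$smoothed <- x$smoothed
  d
}

# shared seed-substream derivation: one master seed, documented per-stage
# offsets, everything kept inside the 32-bit integer range.
derive_seed <- function(master, stage) {
  master <- as.numeric(master)
  (master * 48271 + stage * 1009) %% 2147483647
}
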