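---
title: "Time scales of phenotypic change and coldspot-mimicked selection signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time scales of phenotypic change and coldspot-mimicked selection signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

evoscan addresses two questions that arise when long-term phenotype
monitoring is combined with population genomics:

1. **At what time scale did a trait change?** A single regression over a
   whole monitoring series can be dominated by a level shift early in the
   record; the same data can show a *positive* whole-series trend and a
   *negative* trend once the earliest years are excluded.
2. **Is a genome-scan signal evidence of recent positive selection?** The
   canonical signatures — locally reduced nucleotide diversity, elevated
   long-distance LD, elevated haplotype homozygosity (iES), and a strong
   axis of differentiation (eigenGWAS) — are also produced by a
   recombination coldspot combined with background selection, with no
   beneficial mutation anywhere.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and what the package's validation
does and does not demonstrate.

## Phenotype time-scale analysis

### Breakpoint detection

`max_sel_breakpoint()` scans every between-year boundary of an
individual-level series. For the cut after year $k$, with $n_L$ records on
the left of $N$ total, the statistic is the standardized two-sample linear
statistic

$$T_k = \frac{S_k - n_L\,\bar y}{\sqrt{n_L (N-n_L)\,v/(N-1)}},
\qquad S_k = \sum_{\text{left}} y_i,\quad v = \tfrac1N\sum_i (y_i-\bar y)^2,$$

whose moments are exact under permutation of trait values across
individuals. `maxT` is the maximum of $|T_k|$ over eligible cuts: a cut is
eligible if it leaves at least `minprop` (default 0.1) and at most
`maxprop` (default 0.9) of the observations on one side, and records within
a year are never split. The p-value is the permutation fraction of
shuffled-label `maxT` values at least as large as the observed one, with
the add-one correction $(1 + \#\{T^{(b)} \ge T\})/(B+1)$; the default is
$B = 10{,}000$. A permutation null was chosen over an asymptotic maximally-
selected-statistic approximation because it is exact under exchangeability
at any sample size and makes no distributional assumption about the trait.
Ties in `maxT` are resolved by reporting the earliest boundary, with all
tied boundaries listed. A zero-variance series returns `maxT = 0`, `p = 1`.

The type-I error of this construction is checked in the test suite: on
null series (26 years of 30 birds, no step, no drift) the rejection rate at
$\alpha = 0.05$ over 500 replicates of 1,000 permutations must lie in
[0.03, 0.07], and a one-within-year-SD step is recovered at the exact
injected boundary in at least 95 of 100 replicates.

### Trends, ratio, and the slope scan

`fit_linear_trend()` reports the OLS slope of the trait on calendar year
over individual records and the *partial* F for dropping the year term —
the model comparison `trait ~ [tarsus] + year` versus `trait ~ [tarsus]`.
The term-wise F was chosen (rather than the whole-model F) because the
question being asked is always "does year matter, with or without the
allometric covariate", which contrasts two models that differ only in the
year term. A constant covariate column is dropped (the fit then equals the
unadjusted fit exactly). The allometric ratio analysis divides bill by
tarsus per individual and fits the same model; fitting annual means instead
is available via `annual_means = TRUE`, because either convention is
defensible and they can differ when within-year sample sizes vary.

`slope_scan()` fits one OLS slope for every window of consecutive observed
years with length in `[min_len, max_len]` (defaults 10–25). For a 26-year
series this enumerates $\sum_{l=10}^{25}(27-l) = 152$ windows. Each window
is labeled by whether it contains any configured "early" year, which makes
the dependence of the inferred trend on the analysed window directly
visible.

`loess_smooth()` is the package's own tricube local-polynomial smoother
(span in (0, 1], degree 1 or 2, fitted value returned at each observed
abscissa). It is implemented in-package because the same primitive serves
the annual-mean smoother and all genome-track smoothing; the test suite
verifies it against `stats::loess(..., surface = "direct")` to 1e-8.

`anova_tukey()` fits a two-way additive ANOVA (e.g. country + sex), and
derives a compact letter display from the Tukey HSD table: the letter
groups are the maximal cliques of the "not significantly different at
$\alpha$" graph, so two levels share a letter exactly when their pairwise
Tukey comparison is non-significant.

## Genome-scan statistics

All internal coordinates are 0-based half-open base pairs; conversion to
1-based VCF coordinates happens only at I/O. Windows are `[start,
start + size)` from position 0; a final window truncated by the chromosome
end uses its own length as denominator; window midpoints are the plotting
and contrast coordinates.

- **LD.** The primary dialect is phased haplotype $r^2 = D^2 /
  (p_A(1-p_A)p_B(1-p_B))$; `genotype_r2()` provides the unphased
  genotype-correlation dialect, and every track records which dialect
  produced it in its metadata, because published LD methods frequently leave
  this ambiguous. `long_distance_ld_track()` averages $r^2$ over pairs
  separated by 20–200 kb whose midpoint falls in a 200 kb window (step
  50 kb) — the scale at which a coldspot shows up while ordinary LD has
  already decayed. The default MAF filter for LD and eigenGWAS is 0.05;
  nucleotide diversity applies none, since monomorphic sites are real
  zero-diversity observations.
- **FST.** The Hudson/Bhatia per-SNP estimator was chosen for its closed
  form and its ratio-of-averages robustness; raw values are reported
  without clamping, because the small negative values at undifferentiated
  SNPs are the finite-sample null behaviour and clamping would bias
  averages upward.
- **eigenGWAS.** Dosages are standardized by mean $2\hat p$ and sd
  $\sqrt{2\hat p(1-\hat p)}$, the leading eigenvector of the individual
  covariance is the tested axis ($k = 1$), the per-SNP statistic is the
  1-df score chi-square $n\,r^2$, and genomic control divides by
  $\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549$. Both raw and corrected
  p-values are emitted. A property worth knowing: with an *in-sample*
  eigenvector, $\lambda_{GC}$ exceeds 1 even in a panmictic sample whenever
  the individuals-to-SNPs ratio $n/m$ is not small, because the top
  eigenvalue of a pure-noise standardized covariance sits at the
  Marchenko–Pastur edge $(1+\sqrt{n/m})^2$ — about 1.7 at $n/m = 0.1$. The
  GC-corrected p-values are calibrated (uniform under panmixia) and are the
  inference-grade output; $\lambda_{GC}$ itself approaches 1 only when
  $m \gg n$.
- **EHHS / iES.** For a focal site, EHHS at $x$ is the probability that two
  haplotypes drawn without replacement are identical at every site between
  the focal site and $x$, computed by prefix grouping. The focal site
  itself is *excluded* from the identity interval, which makes
  $\mathrm{EHHS}(0) = 1$ an exact convention rather than a special case;
  the curve is non-increasing outward by refinement. iES integrates EHHS
  over bp by the trapezoid rule in both directions. Truncation rule, frozen
  for reproducibility: segments are accumulated outward and integration
  stops *after* adding the first segment whose far endpoint falls below the
  truncation threshold (default 0.05); if the threshold is never crossed,
  the outermost EHHS value is extended as a constant to the chromosome end.
  iES is reported per Mb.
- **Smoothing.** `smooth_track()` applies the tricube local regression
  (default) or a Gaussian kernel along positions. The default span is
  chosen so the smoothing neighbourhood covers about 1 Mb of the track's
  extent — wide enough to stabilize window noise, narrower than the
  coldspot-scale features of interest. The smoother never states its own
  uncertainty; it is a display and contrast aid.

## The forward simulator

`run_simulation()` is a discrete-generation Wright–Fisher simulator of one
chromosome: parents drawn with probability proportional to multiplicative
fitness over deleterious sites (heterozygote $1+hs$, homozygote $1+s$,
$s \le 0$; no epistasis), crossovers Poisson per map interval with uniform
breakpoint placement, mutations Poisson($\mu L$) per gamete at uniform
integer bp with collisions re-drawn (an infinite-sites approximation;
integer positions make VCF round-trips exact), no beneficial mutations, and
fixed mutations pruned into a substitution log so that diversity statistics
are unaffected. Everything is driven by R's RNG, so a seed makes a run
bit-reproducible. The core is C++ (via Rcpp), as is usual for forward
simulators.

`rescale_params()` applies the standard population-rescaling: $N \to N/Q$,
$\mu \to \mu Q$, $r \to rQ$, $s \to sQ$, burn-in $10N/Q$, preserving
$N\mu$, $Nr$ and $Ns$. Rescaling trades realism of absolute time and of
weakly-selected dynamics for tractable run times; it is rejected when
$sQ \le -1$.

### Study conditions (defaults) and why

The coldspot experiment preset (`desk_scale_params()`): a 5 Mb chromosome
with a central 400 kb coldspot at 1% of the base crossover rate — the same
coldspot-to-chromosome proportion as a 1.6 Mb region on a 20 Mb
chromosome — with $N = 5000$, $\mu = r = 10^{-8}$ per bp, deleterious
fraction 0.3, fixed $s = -0.02$, $h = 0.25$, burn-in $10N$, 100 sampled
haplotypes, rescaled by $Q = 10$. These values realize the qualitative
design — a passerine-like LD decay scale, a weakly-deleterious load strong
enough for background selection ($N h s = 25$ unscaled) and a coldspot long
enough to carry long-range haplotype structure — at about 20–25 s per
replicate on one CPU. With this preset, across 10 replicates, the coldspot
shows lower windowed $\pi$, higher long-distance $r^2$, higher iES and
higher smoothed eigenGWAS $-\log_{10} p$ than the flanks in at least 9 of
10 replicates each (the test suite asserts exactly this), which is the
linked-selection mimicry the package exists to demonstrate.

The **neutral control** (`p_deleterious = 0`) removes the
background-selection *diversity* deficit: the coldspot-to-flank $\pi$ ratio
CI covers 1. The long-distance LD and iES elevations, and with them the
eigenGWAS elevation, *persist* in the neutral control, because they are
consequences of reduced recombination itself, not of selection. This
asymmetry is informative: diversity reduction is the specifically
selective part of the signature, while the LD-family statistics respond to
the recombination landscape with or without selection.

The phenotype generator's defaults (26 years from 1982, 30 birds/year,
bill 13.2 mm sd 0.45, tarsus 19.6 mm sd 0.60, bill–tarsus correlation 0.5,
a +0.25/+0.35 mm step in 1987 and a −0.005/−0.007 mm/yr drift) encode a
great-tit-like series in which the first five years sit on a lower level
and the post-step period drifts down, i.e. the configuration in which
whole-series and post-step regressions disagree in sign. Within-year
sample sizes and variances of the original monitoring data are not public
in any form usable here, so these are stated study conditions, chosen once
for realism, not estimates of any particular dataset.

The structured-genotype generator uses the Balding–Nichols dispersion
model: per-SNP subpopulation frequencies Beta-distributed around an
ancestral frequency with dispersion set by the target $F_{ST}$, giving
closed-form control of expected differentiation; optional "divergent" SNPs
receive an extra $\pm\delta p$ shift as known positives for scan checks.

### Validation scope

Simulator validation uses closed-form coalescent expectations at reduced
scale: chromosome-wide $\pi$ within 10% of $\theta = 4N\mu$ averaged over
10 seeds ($N = 100$, 0.5 Mb), the unfolded site-frequency spectrum
consistent with the $1/i$ neutral expectation over 20 seeds (chi-square
goodness of fit at $\alpha = 0.01$ with the replicate as the sampling
unit, since sites within one replicate share genealogies and pooled site
counts are overdispersed relative to a multinomial), neutral fixation probability of a
standing variant at initial frequency $p$ equal to $p$ within binomial
error over 2,000 tiny-locus replicates, and bitwise determinism under a
fixed seed. Problem sizes in the tests (500 calibration replicates, 10+10
coldspot replicates, 0.2–0.5 Mb validation chromosomes) were chosen as the
smallest scales at which the tested properties are statistically sharp.

What passing these tests shows: the estimators agree with brute-force
definitions, the test statistics are calibrated under their nulls, and the
simulated coldspot reproduces the linked-selection signature. What they do
not show: anything about a particular empirical dataset (the package ships
no field data), demography beyond a single constant-size population,
gene-structure- or annotation-dependent DFEs, or sweep dynamics (beneficial
mutations are deliberately absent from the model).

## Known limitations

- The breakpoint test assumes exchangeability of individuals across years
  under the null; strong within-year autocorrelation of measurement
  conditions would make the permutation null optimistic.
- iES depends on the truncation threshold near chromosome ends; tracks are
  comparable only at a fixed threshold (0.05 by default, recorded in track
  metadata).
- eigenGWAS with one in-sample eigenvector is a structure scan, not an
  association study; its raw $\lambda_{GC}$ is expected to exceed 1 at
  moderate $n/m$ (see above) and only the GC-corrected p-values should be
  interpreted.
- The simulator's rescaling preserves $N\mu$, $Nr$, $Ns$ but shortens
  absolute time scales; haplotype-length statistics are comparable across
  runs with the same $Q$ only.
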