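Package: evoscan
Title: Time-Scale-Aware Phenotype Trends and Linked-Selection Genome Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking at which time scale a quantitative trait has
    evolved, and whether a genome-scan signal attributed to recent positive
    selection is instead compatible with a recombination coldspot plus
    background selection. Provides maximally-selected breakpoint detection
    with permutation p-values, exhaustive consecutive-year slope scans,
    allometry-ratio trend tests, and LOESS smoothing for individual-level
    phenotype series; a genome-scan statistics suite over phased haplotype
    and genotype matrices (LD decay, long-distance r2 tracks, per-SNP Hudson
    FST, eigenGWAS with genomic control, site EHH and integrated EHH (iES),
    windowed nucleotide diversity, and track smoothing); a forward-in-time
    Wright-Fisher simulator of one chromosome with an arbitrary recombination
    map, neutral and deleterious mutations and no beneficial ones; and
    synthetic phenotype and structured-genotype generators with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
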