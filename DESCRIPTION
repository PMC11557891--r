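Package: g12scan
Title: Selective-Sweep Scans on Pseudo-Haploid Ancient DNA with the G12 Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps in low-coverage, unphased genotype data using
    the G12 multi-locus genotype homozygosity statistic computed in fixed SNP
    windows with missing-data-aware clustering. Includes readers for EIGENSTRAT and
    VCF genotype data, transforms that make modern diploid data mimic ancient DNA
    (SNP-panel ascertainment, beta-distributed per-site missingness, cytosine
    deamination damage, pseudo-haploidization), a forward Wright-Fisher simulator of
    hard and soft sweeps (de novo, recurrent-mutation and standing-variation modes)
    under piecewise demography with coalescent-equilibrium initialization, and a
    calibration layer providing simulation-based significance thresholds, peak
    calling, quality-control masks, power/ROC evaluation and neutral z-scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
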