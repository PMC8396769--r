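Package: admixsel
Title: Haplotype Association and Selection Scans for Admixed Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for candidate-gene genetic epidemiology in admixed
    populations: PCA-loading-based tag-SNP prioritization over a gene region,
    EM haplotype frequency estimation from unphased genotypes with
    expected-dosage haplotype association, covariate-adjusted case-control
    association under standard genetic models with BH false-discovery control
    and DerSimonian-Laird random-effects meta-analysis across sites, supervised
    maximum-likelihood admixture estimation from ancestry-informative markers,
    and natural-selection scans at three timescales (windowed Weir-Cockerham
    FST, Tajima's D, and the EHH family: EHH, iHS, xpEHH). Includes
    forward-in-time Wright-Fisher sweep simulation and a synthetic admixed
    cohort generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
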