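Package: rhmscan
Title: Regional Heritability Mapping by Variance-Component Window Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window regional heritability mapping (RHM) for
    quantitative traits in related samples. Builds marker-based genomic
    relationship matrices with homozygosity-corrected diagonals, fits null
    (whole-genome polygenic) and full (whole-genome plus regional) variance
    component models by restricted maximum likelihood, tests each region with
    a boundary likelihood-ratio test, and reports regional and whole-genome
    heritabilities alongside a kinship-aware single-SNP score-test scan for
    comparison. Includes PLINK binary genotype input/output, exact
    Hardy-Weinberg quality control, per-cohort covariate adjustment with
    rank inverse-normal transformation, Bonferroni genome-wide and
    suggestive thresholds for overlapping-window scans, and a gene-dropping
    simulator of related genotype cohorts with regional and polygenic trait
    architecture for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
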