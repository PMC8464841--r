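Package: spermsel
Title: Phenotypic Selection on Ejaculate Traits from Sperm Kinematics and
    SNP Parentage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for measuring univariate and multivariate
    phenotypic selection on ejaculate traits in a wild population. Computes
    sperm kinematics (smoothed average path velocity and linearity) from
    cell tracks, assigns offspring to dam-sire trios from biallelic SNP
    genotypes under a per-allele error model with false-discovery-rate
    control, derives per-male reproductive success and relative fitness,
    estimates Lande-Arnold selection differentials and gradients with
    quasi-Poisson significance tests, and fits a GCV-selected penalized
    cubic spline fitness surface. Includes a synthetic-population generator
    (correlated traits, overdispersed offspring counts under a log-link
    selection surface, Mendelian genotype transmission with genotyping
    error, correlated-random-walk sperm tracks) so the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    ggplot2,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    car,
    vcfR
Config/testthat/edition: 3
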