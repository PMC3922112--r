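Package: gxeherit
Title: SNP-Based Heritability of Genotype-Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide estimation of the phenotypic variance explained by
    genotype-environment (GxE) interactions in population cohorts. Builds
    SNP-derived genetic relationship matrices (GRMs) from PLINK binary
    genotypes, applies marker quality control (missingness, minor allele
    frequency, Hardy-Weinberg exact test), prunes related individuals, and
    fits mixed linear models y = Xb + g + ge + e by average-information REML
    with an environment-masked interaction GRM. Provides the boundary
    likelihood-ratio test for variance components, bivariate REML estimation
    of the cross-environment genetic correlation, a per-SNP two-environment
    slope-difference scan, GRM-based genotype-group norms of reaction, and a
    synthetic cohort generator with known additive and interaction variance
    structure for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
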