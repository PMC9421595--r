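Package: prsmed
Title: Polygenic Risk Score Construction and Amyloid-Mediation Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds clumping-and-thresholding polygenic risk scores (PRS)
    from GWAS summary statistics and genotype dosages, runs covariate-adjusted
    association scans of PRS against CSF biomarkers with rank-based inverse
    normal transformation and Bonferroni control, estimates bootstrap
    mediation of PRS effects on tau biomarkers through binary amyloid status,
    and decomposes a PRS into amyloid-independent and exclusive
    amyloid-dependent variant subsets by leave-one-out screening and nested
    scoring. Includes a synthetic-cohort generator with a planted causal
    architecture (block-LD genotypes in Hardy-Weinberg equilibrium, simulated
    case-control summary statistics, a liability-threshold binary mediator and
    mediated continuous outcomes) so every stage is testable against known
    ground truth, plus variant-level QC (call rate, minor allele frequency,
    exact Hardy-Weinberg test), pairwise LD, genotype principal components,
    and a reproducible end-to-end pipeline driven by a single config.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
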