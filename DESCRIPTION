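Package: twinmeth
Title: Variance Decomposition of DNA Methylation in Longitudinal Twin Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classical twin-design analysis of per-CpG DNA methylation
    measured repeatedly over time. Provides maximum-likelihood ACE/ADE
    variance decomposition with AIC/likelihood-ratio model selection and
    delta-method confidence intervals for heritability, bivariate two-wave
    models estimating cross-wave genetic and environmental correlations,
    intraclass correlations with Fisher z tests for zygosity differences,
    Illumina 450k-style beta/M-value handling with detection-P quality
    control and cell-composition adjustment, and a synthetic twin-cohort
    generator with known ground truth (including CpG-SNP trimodal sites
    under Hardy-Weinberg) so every inference stage can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    numDeriv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
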