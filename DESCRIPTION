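Package: cthaudit
Title: Cell-Type-Heterogeneity-Aware Auditing of Blood DNA Methylation Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit blood-based DNA methylation clocks and
    inflammation scores for confounding by immune cell-type composition.
    Provides reference-based cell-type deconvolution of methylation beta
    values (constrained least squares and robust partial correlation),
    rectified linear clocks with extrinsic age acceleration, a CRP-proxy
    inflammation score computed from z-scored methylomes and a signed CpG
    signature, epigenome-wide association testing with and without
    cell-fraction adjustment, per-cohort association regressions pooled by
    fixed- and random-effects inverse-variance meta-analysis, and
    multivariate-versus-univariate coefficient sign-concordance analysis.
    A bundled multi-cohort simulator generates methylomes as convex
    mixtures of cell-type reference profiles with Dirichlet-distributed
    fractions, condition- and age-dependent composition shifts, cell-type
    specific differentially methylated cytosines, per-cohort batch offsets
    and measurement noise, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
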