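Package: aglsgwas
Title: Approximate Generalized Least Squares GWAS with Additive and
    Dominance Tests and Allelic-Effect Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-marker genome-wide association testing by approximate
    generalized least squares (AGLS): per-SNP genotypic means are fitted to
    phenotypes pre-adjusted by twice the predicted transmitting ability
    (2*PTA), approximating the mixed-model BLUE without inverting the
    phenotypic variance or relationship matrix.  Provides additive and
    dominance contrast t-tests robust to Hardy-Weinberg disequilibrium, a
    quantitative-genetic decomposition of each SNP into allelic means,
    allelic effects, the average effect of gene substitution and the
    dominance effect, an empirical power-law extrapolation for p-values
    below the double-precision floor, conditional regional re-analysis
    after removing an index SNP's genotypic effects, a synthetic-cohort
    generator with configurable Hardy-Weinberg disequilibrium, polygenic
    structure and PTA reliability, and exact small-scale GLS and
    mixed-model-equation solvers for certifying the approximation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
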