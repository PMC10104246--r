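Package: noncogdev
Title: Twin, Genomic SEM and Polygenic Score Analysis of Cognitive and
    Noncognitive Contributions to Academic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and multi-method genetic analysis of how cognitive
    and noncognitive skills contribute to academic achievement across
    development. Provides a synthetic-data engine with full ground-truth
    control (block-LD genotypes for nuclear twin families, two-factor
    Cog/NonCog GWAS architectures, ACE twin phenotypes, and developmental
    outcomes with injectable passive and active/evocative gene-environment
    correlation), together with the analysis stack exercised on it:
    confirmatory factor analysis and standardized regressions with FDR
    correction, maximum-likelihood ACE models (univariate, common pathway,
    trivariate Cholesky), LD score regression with block jackknife, a
    genomic structural equation model implementing GWAS-by-subtraction,
    LDpred-infinitesimal polygenic scores, and population, within-family and
    gene-by-environment regression designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
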