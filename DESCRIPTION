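Package: lmmscan
Title: Two-Step Linear Mixed-Model Association Scans for Single- and
    Multi-Trait Genome-Wide Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association scans under the linear mixed model
    with a polygenic covariance proportional to a kinship matrix. The
    two-step procedure first estimates per-trait variance components
    (total variance and narrow-sense heritability) by profiled maximum
    likelihood on the spectrum of the kinship matrix, then tests every
    SNP by generalized least squares with the trait covariance held
    fixed. Two scan engines are provided: a Cholesky-whitening engine
    for single-trait scans that reuses all covariate cross-products
    across SNPs, and an eigen-rotation engine for multi-trait omics
    scans that rotates genotypes and phenotypes once and fills the
    SNP-by-trait grid with diagonal-weight least-squares solves. A cost
    model selects between the engines, blocked streaming keeps the
    working set within an explicit memory budget, and a synthetic-data
    generator with known ground truth (family-block kinships, ratio
    traits, mean imputation) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
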