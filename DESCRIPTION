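Package: hetscape
Title: Geostatistical Mapping of Fine-Scale Genetic Heterozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for spatial analysis of fine-scale genetic
    heterogeneity in population cohorts sampled over small geographic
    areas. Computes per-land-unit observed heterozygosity from SNP
    genotype tables, builds Thiessen-polygon regionalizations and binary
    contiguity weights, tests global spatial autocorrelation with
    Moran's I under the randomization assumption and by Monte-Carlo
    permutation, fits maximum-likelihood simultaneous autoregressive
    (SAR) error models of heterozygosity on socio-demographic
    covariates with forward model selection, interpolates genetic
    landscapes by regularized splines with tension, and quantifies
    model goodness with standardized pixelwise divergence surfaces.
    Includes a synthetic-study generator so the full pipeline is
    testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
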