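Package: exmirpae
Title: Infant Plasma Extracellular miRNA Biomarkers of Prenatal Alcohol Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for infant plasma extracellular miRNA (exmiRNA)
    qPCR panels as biomarkers of prenatal alcohol exposure. Implements hemolysis
    quality control, non-detect imputation, global-mean delta-CT normalization,
    covariate-adjusted Cohen's d / Hedges' g effect-size screening with
    sex-stratified bootstrap classification, masked within-group correlation
    networks with chromosome annotation and cross-chromosome enrichment, a
    maximum-likelihood confirmatory factor analysis engine with Bartlett
    small-sample correction and omega / maximal-reliability-H coefficients,
    product-of-coefficients mediation with bias-corrected bootstrap intervals,
    and Monte Carlo power, coverage and bias simulations. Ships a synthetic
    cohort generator emulating the two-group, two-timepoint study design so the
    whole pipeline is exercisable without access to the original cohort.
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
    jsonlite,
    yaml,
    withr,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
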