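Package: oysterqg
Title: Quantitative Genetics of Oyster Larval Salinity Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pedigree-based quantitative genetics for larval body size in the
    eastern oyster (Crassostrea virginica) under low versus ambient rearing
    salinity. Implements a modified North Carolina II breeding design,
    additive relationship matrices and their sparse inverses, a Gibbs-sampled
    Bayesian animal model for additive genetic and maternal variance
    components (with a bivariate family-mean model for the cross-environment
    genetic covariance), REML mixed-model ANOVAs with Tukey contrasts for
    transgenerational-plasticity tests, truncation-selection calculations via
    the breeder's equation, and a calibrated synthetic-data generator that
    emulates the breeding experiment end to end.
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
    Matrix,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
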