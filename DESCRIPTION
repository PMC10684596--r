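Package: traitpath
Title: Correlation and Path-Coefficient Analysis for Multi-Environment Crop Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics inference chain for replicated multi-environment
    field trials of the kind used in plant-breeding selection studies: method-of-moments
    variance and covariance component estimation from combined-over-environments ANOVA
    and ANCOVA, genotypic and phenotypic correlation matrices with tabulated-r
    significance marks, multicollinearity screening of predictor traits (variance
    inflation factors, tolerance, eigenvalue condition numbers), and Dewey-Lu path
    coefficient decomposition of yield into direct and indirect effects with percent
    contributions, coefficient of determination, and residual factor. Includes an
    alpha-lattice trial simulator with a configurable genotypic covariance structure,
    modelled on a 120-genotype amaranth evaluation, so the whole chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
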