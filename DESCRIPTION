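Package: AmpliCal
Title: Bayesian Calibration of PCR Bias in Bisulfite Amplicon Methylation Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calibration of bisulfite amplicon sequencing methylation levels
    measured on standard controls of known methylation percentage. Fits a
    family of four Bayesian mixed additive regression models (cubic polynomial
    trend with crossed AMP and CpG random effects, an intrinsic random-walk
    latent field over CpG positions, and correlated random intercepts/slopes)
    by a blocked Gibbs sampler, selects among them by the Deviance Information
    Criterion, and inverts the fitted calibration curve by cubic spline
    interpolation and bounded scalar minimization to correct the observed
    methylation degree in case/control samples. Includes the per-CpG cubic
    polynomial regression baseline, leave-one-out predictive measures (MSEP,
    CV-index), posterior-predictive outlier fences, loss/gain-of-methylation
    classification against a control reference interval, and seed-reproducible
    synthetic data generators for all four models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
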