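#' Construct a calibration design
#'
#' @param ampLevels actual methylation percentages of the standard controls,
#'   strictly increasing, in \[0,100\].
#' @param cpgPositions strictly increasing 1-based CpG positions (bp).
#' @param assayId assay name.
#' @param region optional length-1 `GRanges` with the amplicon coordinates.
#' @return A [CalibrationDesign-class].
#' @examples
#' calibrationDesign(c(0, 25, 50, 75, 100), c(101, 120, 155))
#' @export
calibrationDesign <- function(ampLevels, cpgPositions, assayId = "assay",
                              region = NULL) {
  new("CalibrationDesign", assayId = assayId,
      ampLevels = as.numeric(ampLevels),
      cpgPositions = as.numeric(cpgPositions), region = region)
}

#' Construct a calibration dataset
#'
#' @param design a [CalibrationDesign-class].
#' @param apparent `l x m` matrix of apparent methylation after PCR (percent);
#'   `NA` marks missing cells.
#' @param metadata optional provenance list.
#' @return A [CalibrationData-class].
#' @export
calibrationData <- function(design, apparent, metadata = list()) {
  apparent <- as.matrix(apparent)
  dimnames(apparent) <- list(paste0("amp", design@ampLevels),
                             paste0("cpg", seq_along(design@cpgPositions)))
  new("CalibrationData", design = design, apparent = apparent,
      metadata = metadata)
}

#' Construct a sample dataset
#'
#' @param observed matrix of observed methylation (individuals x CpGs).
#' @param group character or factor of `"control"`/`"case"` labels.
#' @param cpgPositions CpG positions of the columns.
#' @param sampleIds individual identifiers (default `rownames(observed)` or
#'   `s1..sn`).
#' @return A [SampleData-class].
#' @export
sampleData <- function(observed, group, cpgPositions, sampleIds = NULL) {
  observed <- as.matrix(observed)
  if (is.null(sampleIds))
    sampleIds <- rownames(observed) %||% paste0("s", seq_len(nrow(observed)))
  rownames(observed) <- sampleIds
  new("SampleData", sampleIds = as.character(sampleIds),
      group = factor(as.character(group), levels = c("control", "case")),
      observed = observed, cpgPositions = as.numeric(cpgPositions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct generating parameters for simulation
#'
#' Any effect vector left `NULL` is drawn from its model distribution at
#' simulation time; explicit vectors are used as given.
#'
#' @param beta cubic polynomial coefficients (length 4, intercept first).
#' @param sigma2 residual variance.
#' @param tau,upsilon precisions of AMP and CpG random effects
#'   (effect variance is `1/tau`, `1/upsilon`).
#' @param rho RW1 variance scale per bp of CpG separation.
#' @param Sigma 2x2 covariance of per-CpG (intercept, slope) pairs.
#' @param ampEffects,cpgEffects,cpgSlopes,lgf optional explicit effects.
#' @return A [TruthParams-class].
#' @export
truthParams <- function(beta = c(0, 1, 0, 0), sigma2 = 1, tau = 1,
                        upsilon = 1, rho = 0.001,
                        Sigma = diag(c(1, 1e-4)), ampEffects = NULL,
                        cpgEffects = NULL, cpgSlopes = NULL, lgf = NULL) {
  new("TruthParams", beta = as.numeric(beta), ampEffects = ampEffects,
      cpgEffects = cpgEffects, cpgSlopes = cpgSlopes, lgf = lgf,
      sigma2 = sigma2, tau = tau, upsilon = upsilon, rho = rho,
      Sigma = Sigma)
}
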