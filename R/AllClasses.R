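#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges start end width
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

.check_percent <- function(x, what) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad))
    sprintf("%s outside [0,100] at position(s) %s (value %g); methylation is expected in percent",
            what, paste(utils::head(bad, 3L), collapse = ", "), x[bad[1L]])
  else NULL
}

#' Calibration experiment design
#'
#' The design of a standard-control calibration experiment: the actual
#' methylation percentages (AMPs) of the standard-control mixtures, the
#' genomic positions of the CpGs in the amplicon, and (optionally) the
#' amplicon region itself.
#'
#' @slot assayId single character, name of the assay (CGI or DMR symbol).
#' @slot ampLevels numeric vector of AMPs in percent, strictly increasing,
#'   all in \[0,100\], length `l >= 2`.
#' @slot cpgPositions numeric vector of 1-based chromosomal CpG positions
#'   (bp), strictly increasing, length `m >= 1`.
#' @slot region a length-1 [GenomicRanges::GRanges] with the amplicon
#'   coordinates, or `NULL`.  The amplicon length is taken as `end - start`.
#'
#' @exportClass CalibrationDesign
setClass("CalibrationDesign",
  slots = c(assayId = "character", ampLevels = "numeric",
            cpgPositions = "numeric", region = "GRangesOrNULL"))

setValidity("CalibrationDesign", function(object) {
  msg <- character()
  x <- object@ampLevels
  p <- object@cpgPositions
  if (length(object@assayId) != 1L) msg <- c(msg, "assayId must be a single string")
  if (length(x) < 2L) msg <- c(msg, "at least 2 AMP levels are required")
  if (anyNA(x) || any(x < 0 | x > 100)) msg <- c(msg, "AMP levels must lie in [0,100]")
  if (length(x) > 1L && any(diff(x) <= 0)) msg <- c(msg, "AMP levels must be strictly increasing")
  if (length(p) < 1L) msg <- c(msg, "at least one CpG position is required")
  if (anyNA(p)) msg <- c(msg, "CpG positions must be numeric and non-missing")
  if (length(p) > 1L && any(diff(p) <= 0)) msg <- c(msg, "CpG positions must be strictly increasing")
  if (!is.null(object@region)) {
    if (length(object@region) != 1L) msg <- c(msg, "region must be a length-1 GRanges or NULL")
    else if (IRanges::end(object@region) <= IRanges::start(object@region))
      msg <- c(msg, "region end must exceed region start")
  }
  if (length(msg)) msg else TRUE
})

#' Calibration dataset
#'
#' A validated standard-control calibration dataset: the `l x m` matrix of
#' apparent methylation levels after PCR (rows are AMPs, columns are CpGs),
#' together with its design.  Cells may be `NA` (missing measurements or
#' removed CpGs).
#'
#' @slot design a [CalibrationDesign-class].
#' @slot apparent `l x m` numeric matrix, non-missing cells in \[0,100\].
#' @slot metadata free-form list (e.g. injected-outlier provenance).
#'
#' @exportClass CalibrationData
setClass("CalibrationData",
  slots = c(design = "CalibrationDesign", apparent = "matrix", metadata = "list"))

setValidity("CalibrationData", function(object) {
  msg <- character()
  d <- object@design
  y <- object@apparent
  if (nrow(y) != length(d@ampLevels))
    msg <- c(msg, sprintf("apparent matrix has %d rows but design has %d AMP levels",
                          nrow(y), length(d@ampLevels)))
  if (ncol(y) != length(d@cpgPositions))
    msg <- c(msg, sprintf("apparent matrix has %d columns but design has %d CpG positions",
                          ncol(y), length(d@cpgPositions)))
  if (!isTRUE(object@metadata$unbounded)) {
    pm <- .check_percent(as.vector(y), "apparent methylation")
    if (!is.null(pm)) msg <- c(msg, pm)
  }
  if (length(msg)) msg else TRUE
})

#' Sample (case/control) dataset
#'
#' Observed (uncorrected) methylation levels per individual per CpG, aligned
#' to the CpG positions of a calibration design.
#'
#' @slot sampleIds character vector of individual identifiers.
#' @slot group factor with levels `control` and `case`, one per individual.
#' @slot observed numeric matrix, individuals x CpGs, cells in \[0,100\] or `NA`.
#' @slot cpgPositions CpG positions the columns refer to.
#'
#' @exportClass SampleData
setClass("SampleData",
  slots = c(sampleIds = "character", group = "factor",
            observed = "matrix", cpgPositions = "numeric"))

setValidity("SampleData", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (n == 0L) msg <- c(msg, "no individuals")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicated sample ids")
  if (length(object@group) != n) msg <- c(msg, "group labels must match the number of individuals")
  if (!all(levels(object@group) %in% c("control", "case")))
    msg <- c(msg, "group levels must be 'control'/'case'")
  if (nrow(object@observed) != n) msg <- c(msg, "observed matrix rows must match individuals")
  if (ncol(object@observed) != length(object@cpgPositions))
    msg <- c(msg, "observed matrix columns must match CpG positions")
  pm <- .check_percent(as.vector(object@observed), "observed methylation")
  if (!is.null(pm)) msg <- c(msg, pm)
  if (length(msg)) msg else TRUE
})

#' Model specification
#'
#' One of the four calibration models together with its prior configuration.
#' The models share the cubic fixed-effects trend and differ by their random
#' effects: `M1` has AMP effects only; `M2` adds crossed CpG effects; `M3`
#' replaces the CpG effects with an intrinsic first-order random-walk latent
#' field over CpG positions; `M4` adds correlated per-CpG random slopes.
#' Sum-to-zero identifiability constraints on the AMP effects, CpG effects
#' and CpG slopes are always enforced (by a centered orthonormal basis).
#'
#' @slot model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @slot priors prior configuration list, see [defaultPriors()].
#' @slot sumToZero always `TRUE`; kept explicit as the identifiability contract.
#' @slot rw1FirstState `"sumtozero"` (intrinsic field, default) or `"anchored"`
#'   (literal first increment from position 0).
#'
#' @exportClass ModelSpec
setClass("ModelSpec",
  slots = c(model = "character", priors = "list",
            sumToZero = "logical", rw1FirstState = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@model %in% c("M1", "M2", "M3", "M4"))
    msg <- c(msg, "model must be one of M1, M2, M3, M4")
  if (!isTRUE(object@sumToZero)) msg <- c(msg, "sum-to-zero constraints are mandatory")
  if (!object@rw1FirstState %in% c("sumtozero", "anchored"))
    msg <- c(msg, "rw1FirstState must be 'sumtozero' or 'anchored'")
  pv <- .validate_priors(object@priors)
  if (!isTRUE(pv)) msg <- c(msg, pv)
  if (length(msg)) msg else TRUE
})

#' Generating ("truth") parameters for simulation
#'
#' Parameter values used to simulate calibration data from one of the four
#' models.  Effect vectors may be given explicitly; when `NULL` they are
#' drawn from their model distribution (iid normal for AMP/CpG effects,
#' RW1 for the latent field, bivariate normal for intercept/slope pairs).
#'
#' @slot beta numeric(4): cubic polynomial coefficients (intercept first),
#'   on the raw percent scale.
#' @slot ampEffects,cpgEffects,cpgSlopes,lgf optional explicit effect vectors.
#' @slot sigma2 residual variance (percent^2).
#' @slot tau,upsilon precisions of the AMP and CpG effects.
#' @slot rho RW1 variance scale per bp.
#' @slot Sigma 2x2 positive-definite covariance of (intercept, slope) pairs.
#'
#' @exportClass TruthParams
setClass("TruthParams",
  slots = c(beta = "numeric", ampEffects = "numericOrNULL",
            cpgEffects = "numericOrNULL", cpgSlopes = "numericOrNULL",
            lgf = "numericOrNULL", sigma2 = "numeric", tau = "numeric",
            upsilon = "numeric", rho = "numeric", Sigma = "matrix"))

setValidity("TruthParams", function(object) {
  msg <- character()
  if (length(object@beta) != 4L) msg <- c(msg, "beta must have length 4")
  for (s in c("sigma2", "tau", "upsilon", "rho")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0) msg <- c(msg, sprintf("%s must be a single value >= 0", s))
  }
  S <- object@Sigma
  if (!all(dim(S) == c(2L, 2L)) || abs(S[1L, 2L] - S[2L, 1L]) > 1e-12)
    msg <- c(msg, "Sigma must be a symmetric 2x2 matrix")
  else if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < 0))
    msg <- c(msg, "Sigma must be positive semi-definite")
  if (length(msg)) msg else TRUE
})

#' Posterior fit of a calibration model
#'
#' The result of fitting one of the four calibration models by the blocked
#' Gibbs sampler: posterior draws and marginal summaries of all parameters,
#' per-cell fitted means and predictive quantiles, DIC, and convergence
#' diagnostics.
#'
#' @slot model model identifier.
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot data the [CalibrationData-class] the model was fitted to.
#' @slot draws list of posterior draw matrices (`beta`, `amp`, `cpg`, `lgf`,
#'   `slope`, `sigma2`, `tau`, `upsilon`, `rho`, `SigmaInv`, `lp`, `yrep`).
#' @slot summary list of summary data frames (mean and 2.5/25/50/75/97.5%
#'   quantiles) per parameter block.
#' @slot fitted `l x m` matrix of posterior-mean fitted values, clipped to
#'   \[0,100\].
#' @slot dic deviance information criterion (conditional deviance).
#' @slot dicInfo list with `Dbar`, `Dhat`, `pD` and the marginal variant.
#' @slot diagnostics list: split-Rhat per monitored scalar, `converged`,
#'   `seed`.
#' @slot engine the engine options used.
#'
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  slots = c(model = "character", spec = "ModelSpec", data = "CalibrationData",
            draws = "list", summary = "list", fitted = "matrix",
            dic = "numeric", dicInfo = "list", diagnostics = "list",
            engine = "list"))

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (any(object@fitted < 0 | object@fitted > 100, na.rm = TRUE))
    msg <- c(msg, "fitted means must be clipped to [0,100]")
  blks <- c("amp", "cpg", "slope",
            if (object@spec@rw1FirstState == "sumtozero") "lgf")
  for (blk in blks) {
    dr <- object@draws[[blk]]
    if (!is.null(dr) && ncol(dr) > 0L) {
      s <- abs(sum(colMeans(dr)))
      if (s > 1e-6) msg <- c(msg, sprintf("posterior-mean %s effects must sum to zero (got %g)", blk, s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-CpG forward calibration curve
#'
#' The evaluable forward map `g_j(x)` for every CpG: posterior-mean cubic
#' polynomial + natural cubic spline through the posterior means of the AMP
#' random effects + a per-CpG offset `C_j(x)` whose form depends on the model
#' (`0` for M1, CpG effect for M2, latent-field value for M3, CpG effect +
#' slope * x for M4).
#'
#' @slot model model identifier the curve derives from.
#' @slot beta posterior-mean polynomial coefficients (raw percent scale).
#' @slot knotsX AMP levels (spline knot abscissae).
#' @slot knotsEta posterior means of the AMP random effects (knot ordinates).
#' @slot cpgPositions CpG positions.
#' @slot cpgEffects,cpgSlopes,lgf per-CpG offset components (zeros when the
#'   model lacks the component).
#' @slot monotone logical per CpG: is `g_j` non-decreasing on a 0.1-step grid.
#'
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(model = "character", beta = "numeric", knotsX = "numeric",
            knotsEta = "numeric", cpgPositions = "numeric",
            cpgEffects = "numeric", cpgSlopes = "numeric", lgf = "numeric",
            monotone = "logical"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  m <- length(object@cpgPositions)
  if (length(object@beta) != 4L) msg <- c(msg, "beta must have length 4")
  if (length(object@knotsX) != length(object@knotsEta))
    msg <- c(msg, "knot abscissae and ordinates differ in length")
  if (anyDuplicated(object@knotsX)) msg <- c(msg, "duplicate spline knot abscissae")
  for (s in c("cpgEffects", "cpgSlopes", "lgf", "monotone"))
    if (length(slot(object, s)) != m) msg <- c(msg, sprintf("%s must have one entry per CpG", s))
  if (length(msg)) msg else TRUE
})

#' Per-CpG cubic polynomial regression (CPR) fit
#'
#' The baseline calibration: an ordinary least-squares cubic polynomial of
#' apparent on actual methylation fitted independently for each CpG.
#'
#' @slot coef 4 x m matrix of coefficients (intercept, x, x^2, x^3 rows).
#' @slot sigma2 per-CpG residual variance (NA when there are no residual df).
#' @slot ampLevels AMP levels used in the fit.
#' @slot cpgPositions CpG positions.
#'
#' @exportClass CPRFit
setClass("CPRFit",
  slots = c(coef = "matrix", sigma2 = "numeric",
            ampLevels = "numeric", cpgPositions = "numeric"))

#' PCR-bias correction result
#'
#' Corrected methylation degrees per individual per CpG, in long form.
#'
#' @slot table data.frame with columns `id`, `group`, `cpg_pos`, `observed`,
#'   `corrected`.
#' @slot method `"bayes"` (calibration-curve inversion) or `"cpr"`.
#'
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  slots = c(table = "data.frame", method = "character"))

setValidity("CorrectionResult", function(object) {
  msg <- character()
  need <- c("id", "group", "cpg_pos", "observed", "corrected")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  else {
    cc <- object@table$corrected
    if (any(!is.na(cc) & (cc < 0 | cc > 100))) msg <- c(msg, "corrected values must lie in [0,100]")
  }
  if (!object@method %in% c("bayes", "cpr")) msg <- c(msg, "method must be 'bayes' or 'cpr'")
  if (length(msg)) msg else TRUE
})

#' Control reference interval
#'
#' The healthy-control reference interval on corrected methylation:
#' `center +/- k * sd`, clipped to \[0,100\].
#'
#' @slot center,sd pooled mean and SD of the control corrected degrees.
#' @slot k SD multiplier (3 corresponds to a two-sided alpha of 0.0027).
#' @slot lower,upper interval bounds.
#'
#' @exportClass ReferenceInterval
setClass("ReferenceInterval",
  slots = c(center = "numeric", sd = "numeric", k = "numeric",
            lower = "numeric", upper = "numeric"))

setValidity("ReferenceInterval", function(object) {
  if (object@lower > object@upper) "lower bound exceeds upper bound" else TRUE
})

#' Loss/normal/gain classification result
#'
#' Per-patient classification of the mean corrected methylation degree
#' against a control reference interval.
#'
#' @slot table data.frame with columns `id`, `mean`, `rangeMin`, `rangeMax`,
#'   `call` (`loss`/`normal`/`gain`) and `uncertain` (range crosses a bound).
#' @slot interval the [ReferenceInterval-class] used.
#'
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  slots = c(table = "data.frame", interval = "ReferenceInterval"))
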