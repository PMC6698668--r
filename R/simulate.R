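#' Simulate a calibration experiment from a generating model
#'
#' Draws `y_ij = beta'(1,x,x^2,x^3) + RE_ij + N(0, sigma2)` on the design
#' grid, where the random effects follow the generating model: iid
#' `N(0, 1/tau)` AMP effects (all models), iid `N(0, 1/upsilon)` CpG effects
#' (M2), an RW1 walk over CpG positions with increment variance
#' `rho * |p_j - p_{j-1}|` (M3, started at 0), or bivariate-normal
#' (intercept, slope) pairs with covariance `Sigma` (M4).  Effects fixed in
#' `truth` are used as given; draws are iid (uncentered), matching the
#' generative model rather than the inferential sum-to-zero
#' reparameterization (see [identifiedTruth()]).
#'
#' @param design a [CalibrationDesign-class].
#' @param truth a [TruthParams-class].
#' @param model generating model id.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param clip clip simulated values to \[0,100\] (default); turn off for
#'   exact moment checks.
#' @return List with `data` (a [CalibrationData-class]) and `truth` (a list
#'   recording the realized effects, seed and model).
#' @export
simulateCalibration <- function(design, truth, model = "M2", seed = 1L,
                                clip = TRUE) {
  stopifnot(is(design, "CalibrationDesign"), is(truth, "TruthParams"))
  if (!model %in% c("M1", "M2", "M3", "M4")) stop("unknown model id: ", model)
  if (model != "M4" && !is.null(truth@cpgSlopes))
    stop("random slopes are only consistent with model M4")
  l <- length(design@ampLevels)
  m <- length(design@cpgPositions)
  .with_seed(seed, {
    amp <- truth@ampEffects %||% stats::rnorm(l, 0, sqrt(1 / truth@tau))
    if (length(amp) != l) stop("ampEffects must have one entry per AMP level")
    cpg <- slope <- lgf <- numeric(m)
    if (model %in% c("M2", "M4"))
      cpg <- truth@cpgEffects %||% stats::rnorm(m, 0, sqrt(1 / truth@upsilon))
    if (model == "M4") {
      if (!is.null(truth@cpgSlopes) || !is.null(truth@cpgEffects)) {
        slope <- truth@cpgSlopes %||% numeric(m)
      } else {
        ch <- chol(truth@Sigma)
        W <- matrix(stats::rnorm(2L * m), m, 2L) %*% ch
        cpg <- W[, 1L]; slope <- W[, 2L]
      }
    }
    if (model == "M3")
      lgf <- truth@lgf %||% cumsum(stats::rnorm(m, 0,
               sqrt(truth@rho * c(design@cpgPositions[1L] * 0,
                                  diff(design@cpgPositions)))))
    x <- design@ampLevels
    mean_grid <- outer(drop(.poly_basis(x) %*% truth@beta) + amp, cpg + lgf, `+`) +
      outer(x, slope)
    y <- mean_grid + matrix(stats::rnorm(l * m, 0, sqrt(truth@sigma2)), l, m)
    if (clip) y <- .clip01(y)
    list(data = calibrationData(design, y,
           metadata = if (clip) list() else list(unbounded = TRUE)),
         truth = list(model = model, seed = seed, beta = truth@beta,
                      ampEffects = amp, cpgEffects = cpg, cpgSlopes = slope,
                      lgf = lgf, sigma2 = truth@sigma2, tau = truth@tau,
                      upsilon = truth@upsilon, rho = truth@rho,
                      Sigma = truth@Sigma))
  })
}

#' Sum-to-zero-identified reparameterization of a realized truth
#'
#' The generative model draws effects iid, so the raw intercept is
#' confounded with the mean AMP and CpG effects and the raw linear
#' coefficient with the mean random slope.  This helper recenters the
#' realized effects and absorbs their means into `beta`, yielding the
#' parameterization the sampler identifies; use it as the target of
#' parameter-recovery checks.
#'
#' @param truth the `truth` list returned by [simulateCalibration()].
#' @return The same list with centered effects and adjusted `beta`.
#' @export
identifiedTruth <- function(truth) {
  t2 <- truth
  t2$beta[1L] <- truth$beta[1L] + mean(truth$ampEffects) +
    mean(truth$cpgEffects) + mean(truth$lgf)
  t2$beta[2L] <- truth$beta[2L] + mean(truth$cpgSlopes)
  t2$ampEffects <- truth$ampEffects - mean(truth$ampEffects)
  t2$cpgEffects <- truth$cpgEffects - mean(truth$cpgEffects)
  t2$cpgSlopes <- truth$cpgSlopes - mean(truth$cpgSlopes)
  t2$lgf <- truth$lgf - mean(truth$lgf)
  t2
}

#' Simulate a case/control cohort through a known calibration curve
#'
#' Pushes true methylation degrees through the forward map (the PCR-bias
#' distortion) and adds measurement noise:
#' `observed_sj = g_j(true_sj) + N(0, noiseSd^2)`, clipped to \[0,100\].
#'
#' @param curve a [CalibrationCurve-class].
#' @param trueDegrees matrix (individuals x CpGs) of true methylation
#'   degrees in \[0,100\], or a vector of per-individual degrees shared
#'   across CpGs.
#' @param group `"control"`/`"case"` label per individual.
#' @param noiseSd measurement noise SD in percent.
#' @param seed integer seed.
#' @param sampleIds optional ids.
#' @return List with `samples` (a [SampleData-class]) and `truth` (the true
#'   degree matrix).
#' @export
simulateCohort <- function(curve, trueDegrees, group, noiseSd = 1, seed = 1L,
                           sampleIds = NULL) {
  m <- length(curve@cpgPositions)
  if (is.null(dim(trueDegrees)))
    trueDegrees <- matrix(trueDegrees, length(trueDegrees), m)
  if (any(trueDegrees < 0 | trueDegrees > 100))
    stop("true methylation degrees must lie in [0,100]")
  n <- nrow(trueDegrees)
  stopifnot(length(group) == n)
  .with_seed(seed, {
    obs <- matrix(NA_real_, n, m)
    for (j in seq_len(m))
      obs[, j] <- evalCurve(curve, j, trueDegrees[, j])
    obs <- .clip01(obs + matrix(stats::rnorm(n * m, 0, noiseSd), n, m))
    list(samples = sampleData(obs, group, curve@cpgPositions,
                              sampleIds = sampleIds),
         truth = trueDegrees)
  })
}

#' Inject outlier shifts into calibration cells
#'
#' @param data a [CalibrationData-class].
#' @param cells 2-column matrix (or vector of length 2) of (AMP index, CpG
#'   index) pairs.
#' @param offset shift in percentage points; results are clipped to
#'   \[0,100\].
#' @return The modified [CalibrationData-class]; injected cells are recorded
#'   in `metadata$injectedOutliers`.
#' @export
injectOutliers <- function(data, cells, offset) {
  stopifnot(is(data, "CalibrationData"))
  cells <- matrix(as.integer(cells), ncol = 2L)
  y <- data@apparent
  if (any(cells[, 1L] < 1L | cells[, 1L] > nrow(y) |
          cells[, 2L] < 1L | cells[, 2L] > ncol(y)))
    stop("outlier cell index out of range")
  y[cells] <- .clip01(y[cells] + offset)
  md <- data@metadata
  md$injectedOutliers <- rbind(md$injectedOutliers,
                               cbind(cells, offset = offset))
  calibrationData(data@design, y, metadata = md)
}

#' Packaged amplicon assay designs
#'
#' Eight bisulfite amplicon assays (two CpG islands on the SDHC promoter and
#' six imprinted DMRs) with their hg19 regions and per-amplicon CpG counts,
#' as used with five standard controls at 0/25/50/75/100% actual
#' methylation.  True per-CpG coordinates within each amplicon are not part
#' of the metadata, so CpG positions are synthesized evenly spaced inside
#' the region (sufficient for distance-based dependence structure).
#'
#' @return Named list of [CalibrationDesign-class] objects.
#' @examples
#' assayDesigns()[["KCNQ1OT1"]]
#' @export
assayDesigns <- function() {
  meta <- data.frame(
    assay = c("SDHC_CpG17", "SDHC_CpG27", "PLAGL1", "GRB10",
              "MEST", "H19_IGF2", "KCNQ1OT1", "MEG3"),
    chrom = c("chr1", "chr1", "chr6", "chr7", "chr7", "chr11", "chr11", "chr14"),
    start = c(161283846, 161284062, 144329490, 50849242,
              130131671, 2019495, 2721402, 101293752),
    end = c(161284062, 161284311, 144329722, 50849440,
            130131913, 2019709, 2721616, 101293975),
    ncpg = c(11L, 16L, 28L, 8L, 5L, 12L, 17L, 11L))
  out <- lapply(seq_len(nrow(meta)), function(k) {
    r <- meta[k, ]
    pos <- round(seq(r$start + 1, r$end, length.out = r$ncpg))
    region <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
    calibrationDesign(c(0, 25, 50, 75, 100), pos, assayId = r$assay,
                      region = region)
  })
  stats::setNames(out, meta$assay)
}

#' Eight-point standard-control AMP levels
#'
#' The eight-level standard-control series used with pyrosequencing-style
#' assays: 0, 12.5, 25, 37.5, 50, 62.5, 87.5 and 100% actual methylation.
#'
#' @return Numeric vector of 8 AMP levels.
#' @export
eightPointAmpLevels <- function() c(0, 12.5, 25, 37.5, 50, 62.5, 87.5, 100)
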