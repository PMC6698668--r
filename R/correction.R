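#' Natural cubic spline through the posterior AMP effects
#'
#' Interpolates the posterior means of the AMP random effects at the AMP
#' levels by a natural cubic spline (second derivative zero at the end
#' knots; linear interpolation when only two knots exist).  The interpolant
#' passes exactly through every knot.  Evaluation outside the knot range
#' errors: calibration designs span 0-100%, so no extrapolation is needed.
#'
#' @param fit a [CalibrationFit-class], or a list with `knotsX`/`knotsEta`.
#' @return A function `eta(x)` defined on `[min(knots), max(knots)]`.
#' @export
interpolateAmpEffects <- function(fit) {
  if (is(fit, "CalibrationFit")) {
    kx <- fit@data@design@ampLevels
    ke <- colMeans(fit@draws$amp)
  } else {
    kx <- fit$knotsX; ke <- fit$knotsEta
  }
  .amp_spline(kx, ke)
}

.amp_spline <- function(kx, ke, extrapolate = FALSE) {
  if (anyDuplicated(kx)) stop("duplicate spline knot abscissae")
  f <- if (length(kx) == 2L) stats::approxfun(kx, ke, rule = 2)
       else stats::splinefun(kx, ke, method = "natural")
  rng <- range(kx)
  function(x) {
    if (!extrapolate && any(x < rng[1L] - 1e-9 | x > rng[2L] + 1e-9))
      stop(sprintf("spline evaluation outside the knot range [%g, %g]", rng[1L], rng[2L]))
    f(x)
  }
}

#' Build the per-CpG forward calibration curves from a fit
#'
#' The forward map of CpG `j` is
#' `g_j(x) = E(beta|y)'(1,x,x^2,x^3) + eta(x) + C_j(x)`, where `eta` is the
#' natural cubic spline through the posterior means of the AMP effects and
#' `C_j` is 0 (M1), the CpG effect (M2), the latent-field value (M3), or
#' CpG effect + slope * x (M4), all at their posterior means.  Monotonicity
#' of each `g_j` is checked on a 0.1-step grid.
#'
#' @param fit a [CalibrationFit-class].
#' @return A [CalibrationCurve-class].
#' @export
buildCurve <- function(fit) {
  stopifnot(is(fit, "CalibrationFit"))
  d <- fit@data@design
  m <- length(d@cpgPositions)
  zero <- numeric(m)
  cpgE <- if (!is.null(fit@draws$cpg)) colMeans(fit@draws$cpg) else zero
  slp <- if (!is.null(fit@draws$slope)) colMeans(fit@draws$slope) else zero
  lgf <- if (!is.null(fit@draws$lgf)) colMeans(fit@draws$lgf) else zero
  curve <- new("CalibrationCurve", model = fit@model,
               beta = colMeans(fit@draws$beta),
               knotsX = d@ampLevels, knotsEta = colMeans(fit@draws$amp),
               cpgPositions = d@cpgPositions,
               cpgEffects = cpgE, cpgSlopes = slp, lgf = lgf,
               monotone = rep(NA, m))
  grid <- seq(min(d@ampLevels), max(d@ampLevels), by = 0.1)
  gv <- evalCurve(curve, seq_len(m), grid)
  curve@monotone <- apply(gv, 1L, function(g) all(diff(g) >= -1e-9))
  curve
}

#' Evaluate forward calibration curves
#'
#' @param curve a [CalibrationCurve-class].
#' @param j CpG index or vector of indices.
#' @param x AMP value(s) in percent, within the knot range.
#' @return Numeric matrix `length(j) x length(x)` (dropped to a vector when
#'   `j` is scalar).
#' @export
evalCurve <- function(curve, j, x) {
  eta <- .amp_spline(curve@knotsX, curve@knotsEta)
  common <- drop(.poly_basis(x) %*% curve@beta) + eta(x)
  out <- t(vapply(j, function(jj) {
    common + curve@cpgEffects[jj] + curve@lgf[jj] + curve@cpgSlopes[jj] * x
  }, numeric(length(x))))
  if (length(j) == 1L) drop(out) else out
}

# Bounded inversion of a scalar forward map g on [lo, hi]: minimize
# (yobs - g(x))^2.  Monotone maps use optimize directly; otherwise a global
# 0.1-step grid scan brackets the optimum before local refinement.
.invert_map <- function(g, yobs, lo, hi, monotone) {
  obj <- function(x) (yobs - g(x))^2
  if (isTRUE(monotone)) {
    if (yobs <= g(lo)) return(lo)
    if (yobs >= g(hi)) return(hi)
    return(stats::optimize(obj, c(lo, hi), tol = 1e-6)$minimum)
  }
  grid <- seq(lo, hi, by = 0.1)
  k <- which.min(obj(grid))
  lo2 <- grid[max(1L, k - 1L)]; hi2 <- grid[min(length(grid), k + 1L)]
  cand <- stats::optimize(obj, c(lo2, hi2), tol = 1e-6)$minimum
  best <- c(lo, hi, cand)
  best[which.min(obj(best))]
}

#' Correct a single observation through a calibration curve
#'
#' Inverts the forward map of CpG `j` at the observed methylation level by
#' bounded scalar minimization of the squared deviation on \[0,100\];
#' boundary solutions are allowed, and non-monotone curves fall back to a
#' global grid scan (with a warning).
#'
#' @param curve a [CalibrationCurve-class].
#' @param j CpG index.
#' @param yObs observed methylation (percent).
#' @return Corrected methylation degree in \[0,100\].
#' @export
correctObservation <- function(curve, j, yObs) {
  if (is.na(yObs)) return(NA_real_)
  if (yObs < 0 || yObs > 100) stop("observed methylation must lie in [0,100]")
  if (!curve@monotone[j])
    warning(sprintf("calibration curve for CpG %d is not monotone; using global grid search", j))
  g <- function(x) evalCurve(curve, j, x)
  .clip01(.invert_map(g, yObs, min(curve@knotsX), max(curve@knotsX),
                      curve@monotone[j]))
}

#' Correct a sample dataset through a calibration curve
#'
#' Applies [correctObservation()] cell-wise; the per-individual mean is taken
#' over non-missing CpGs.
#'
#' @param curve a [CalibrationCurve-class].
#' @param samples a [SampleData-class]; its CpG positions must match the
#'   curve's.
#' @return A [CorrectionResult-class] (method `"bayes"`).
#' @export
correctSamples <- function(curve, samples) {
  .correct_samples(samples, curve@cpgPositions, "bayes",
                   function(j, y) correctObservation(curve, j, y))
}

.correct_samples <- function(samples, positions, method, corrector) {
  stopifnot(is(samples, "SampleData"))
  common <- intersect(samples@cpgPositions, positions)
  if (length(common) == 0L) stop("no overlapping CpGs between curve and samples")
  scol <- match(common, samples@cpgPositions)
  ccol <- match(common, positions)
  rows <- list()
  for (s in seq_along(samples@sampleIds)) {
    obs <- samples@observed[s, scol]
    corr <- vapply(seq_along(common),
                   function(k) corrector(ccol[k], obs[k]), 0)
    rows[[s]] <- data.frame(id = samples@sampleIds[s],
                            group = as.character(samples@group[s]),
                            cpg_pos = common, observed = as.numeric(obs),
                            corrected = corr, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$id, tab$cpg_pos), , drop = FALSE]
  rownames(tab) <- NULL
  new("CorrectionResult", table = tab, method = method)
}

#' Per-individual mean corrected degree
#'
#' @param result a [CorrectionResult-class].
#' @return Named numeric vector of means across non-missing CpGs.
#' @export
correctedMeans <- function(result) {
  stopifnot(is(result, "CorrectionResult"))
  v <- tapply(result@table$corrected, result@table$id,
              function(v) mean(v, na.rm = TRUE))
  stats::setNames(as.numeric(v), names(v))
}

#' Fit the per-CpG cubic polynomial regression baseline
#'
#' Ordinary least-squares cubic fit of apparent on actual methylation,
#' independently per CpG (via [stats::lm()] with raw polynomial terms).
#'
#' @param data a [CalibrationData-class]; each CpG needs at least 4 distinct
#'   AMP levels with data.
#' @return A [CPRFit-class].
#' @export
fitCPR <- function(data) {
  stopifnot(is(data, "CalibrationData"))
  d <- data@design
  x <- d@ampLevels
  m <- length(d@cpgPositions)
  coef <- matrix(NA_real_, 4L, m,
                 dimnames = list(c("b0", "b1", "b2", "b3"), NULL))
  s2 <- numeric(m)
  for (j in seq_len(m)) {
    yj <- data@apparent[, j]
    ok <- !is.na(yj)
    if (length(unique(x[ok])) < 4L)
      stop(sprintf("CpG %d has fewer than 4 distinct AMP levels with data; the cubic is underdetermined", j))
    fm <- stats::lm(yj[ok] ~ x[ok] + I(x[ok]^2) + I(x[ok]^3))
    coef[, j] <- stats::coef(fm)
    rdf <- fm$df.residual
    s2[j] <- if (rdf > 0) sum(stats::resid(fm)^2) / rdf else NA_real_
  }
  new("CPRFit", coef = coef, sigma2 = s2, ampLevels = x,
      cpgPositions = d@cpgPositions)
}

#' Evaluate a CPR forward curve
#'
#' @param cpr a [CPRFit-class].
#' @param j CpG index.
#' @param x AMP value(s) in percent.
#' @return Predicted apparent methylation.
#' @export
cprPredict <- function(cpr, j, x) {
  drop(.poly_basis(x) %*% cpr@coef[, j])
}

#' Correct an observation through the CPR baseline
#'
#' Bounded minimization of the squared deviation from the per-CpG cubic, on
#' \[0,100\]; non-monotone cubics fall back to a grid scan.
#'
#' @inheritParams cprPredict
#' @param yObs observed methylation (percent).
#' @return Corrected methylation degree in \[0,100\].
#' @export
cprCorrect <- function(cpr, j, yObs) {
  if (is.na(yObs)) return(NA_real_)
  if (yObs < 0 || yObs > 100) stop("observed methylation must lie in [0,100]")
  g <- function(x) cprPredict(cpr, j, x)
  grid <- seq(0, 100, by = 0.1)
  mono <- all(diff(g(grid)) >= -1e-9)
  .clip01(.invert_map(g, yObs, 0, 100, mono))
}

#' Correct a sample dataset through the CPR baseline
#'
#' @param cpr a [CPRFit-class].
#' @param samples a [SampleData-class].
#' @return A [CorrectionResult-class] (method `"cpr"`).
#' @export
cprCorrectSamples <- function(cpr, samples) {
  .correct_samples(samples, cpr@cpgPositions, "cpr",
                   function(j, y) cprCorrect(cpr, j, y))
}

#' Serialize / restore a calibration curve as JSON
#'
#' @param curve a [CalibrationCurve-class].
#' @param path output (input) file path.
#' @return `curveFromJSON` returns the restored [CalibrationCurve-class].
#' @export
curveToJSON <- function(curve, path) {
  obj <- list(model = curve@model, beta = curve@beta, knotsX = curve@knotsX,
              knotsEta = curve@knotsEta, cpgPositions = curve@cpgPositions,
              cpgEffects = curve@cpgEffects, cpgSlopes = curve@cpgSlopes,
              lgf = curve@lgf, monotone = curve@monotone)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname curveToJSON
#' @export
curveFromJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve", model = o$model, beta = as.numeric(o$beta),
      knotsX = as.numeric(o$knotsX), knotsEta = as.numeric(o$knotsEta),
      cpgPositions = as.numeric(o$cpgPositions),
      cpgEffects = as.numeric(o$cpgEffects),
      cpgSlopes = as.numeric(o$cpgSlopes), lgf = as.numeric(o$lgf),
      monotone = as.logical(o$monotone))
}
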