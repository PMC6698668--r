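#' Residual sum of squares over a calibration grid
#'
#' `RSS = sum_ij (y_ij - E(Y_ij|x))^2` over non-missing cells.
#'
#' @param predicted `l x m` matrix of predictions.
#' @param data a [CalibrationData-class].
#' @return Non-negative scalar.
#' @export
residualSumSquares <- function(predicted, data) {
  stopifnot(is(data, "CalibrationData"))
  y <- data@apparent
  if (!all(dim(predicted) == dim(y)))
    stop(sprintf("prediction matrix is %d x %d but data grid is %d x %d",
                 nrow(predicted), ncol(predicted), nrow(y), ncol(y)))
  sum((y - predicted)^2, na.rm = TRUE)
}

.delete_cells <- function(data, cells) {
  y <- data@apparent
  y[cells] <- NA
  calibrationData(data@design, y, metadata = data@metadata)
}

# Leave-one-out prediction of the Bayesian model after a deletion.
.bayes_predict_deleted <- function(fit, scenario, iobs, jobs) {
  d <- fit@data@design
  bhat <- colMeans(fit@draws$beta)
  eta <- colMeans(fit@draws$amp)
  x <- d@ampLevels[iobs]
  fixedpart <- drop(.poly_basis(x) %*% bhat)
  pred <- switch(scenario,
    cell = fixedpart + eta[iobs] +
      vapply(seq_along(jobs), function(k) .cj_mean(fit, jobs[k], x[k]), 0),
    # removed CpG: only terms common to all CpGs are available
    cpg = fixedpart + eta[iobs],
    # removed AMP: its random effect is interpolated from the remaining ones
    amp = {
      keep <- setdiff(seq_along(d@ampLevels), unique(iobs))
      etaf <- .amp_spline(d@ampLevels[keep], eta[keep], extrapolate = TRUE)
      fixedpart + etaf(x) +
        vapply(seq_along(jobs), function(k) .cj_mean(fit, jobs[k], x[k]), 0)
    })
  .clip01(pred)
}

#' Leave-one-out mean squared error of prediction
#'
#' `MSEP = sum_ij (y_ij - E(Y_ij | x_deleted))^2 / n` with refit-per-deletion
#' leave-one-out in three scenarios: `"cell"` deletes one CpG-AMP
#' combination at a time, `"cpg"` deletes a whole CpG, `"amp"` deletes one
#' AMP level from all CpGs.  For the Bayesian model, a deleted CpG is
#' predicted from the terms common to all CpGs (fixed effects + AMP effect)
#' and a deleted AMP's random effect by natural-spline interpolation of the
#' remaining AMP effects.  For the CPR baseline a deleted CpG is predicted
#' by [flankingWeightedPrediction()].
#'
#' @param data a [CalibrationData-class].
#' @param method `"bayes"` or `"cpr"`.
#' @param scenario `"cell"`, `"cpg"` or `"amp"`.
#' @param spec [ModelSpec-class] used for Bayesian refits.
#' @param engine engine options for the refits; the default uses a reduced
#'   draw count and a single chain, and every refit reuses the same seed so
#'   the measure is deterministic.
#' @return MSEP (scalar); the number of refits performed is attached as
#'   attribute `"refits"`.
#' @export
msep <- function(data, method = c("bayes", "cpr"),
                 scenario = c("cell", "cpg", "amp"),
                 spec = makeModelSpec("M2"),
                 engine = engineOptions(chains = 1L, iter = 400L, warmup = 150L)) {
  method <- match.arg(method)
  scenario <- match.arg(scenario)
  y <- data@apparent
  l <- nrow(y); m <- ncol(y)
  obs <- which(!is.na(y))
  iobs <- ((obs - 1L) %% l) + 1L
  jobs <- ((obs - 1L) %/% l) + 1L
  deletions <- switch(scenario,
    cell = lapply(seq_along(obs), function(k)
      list(cells = obs[k], i = iobs[k], j = jobs[k])),
    cpg = lapply(sort(unique(jobs)), function(j)
      list(cells = obs[jobs == j], i = iobs[jobs == j], j = rep(j, sum(jobs == j)))),
    amp = lapply(sort(unique(iobs)), function(i)
      list(cells = obs[iobs == i], i = rep(i, sum(iobs == i)), j = jobs[iobs == i])))
  sse <- 0; refits <- 0L
  for (del in deletions) {
    reduced <- .delete_cells(data, del$cells)
    pred <- if (method == "bayes") {
      fit <- fitCalibration(reduced, spec, engine)
      refits <- refits + 1L
      .bayes_predict_deleted(fit, scenario, del$i, del$j)
    } else {
      .cpr_predict_deleted(reduced, data, scenario, del$i, del$j)
    }
    if (method == "cpr") refits <- refits + 1L
    sse <- sse + sum((y[del$cells] - pred)^2)
  }
  out <- sse / length(obs)
  attr(out, "refits") <- refits
  out
}

.cpr_predict_deleted <- function(reduced, full, scenario, iobs, jobs) {
  if (scenario == "cpg") {
    # other CpGs' fits are unaffected by the deletion; predict the excluded
    # CpG from its flanking curves
    cpr <- fitCPR(full)
    j <- jobs[1L]
    fl <- flankingWeightedPrediction(cpr, full@design, j)
    return(fl[iobs])
  }
  x <- full@design@ampLevels
  vapply(seq_along(iobs), function(k) {
    j <- jobs[k]
    yj <- reduced@apparent[, j]
    ok <- !is.na(yj)
    if (length(unique(x[ok])) < 4L)
      stop(sprintf("deletion leaves CpG %d with fewer than 4 distinct AMPs; CPR is underdetermined", j))
    fm <- stats::lm(yj[ok] ~ x[ok] + I(x[ok]^2) + I(x[ok]^3))
    xi <- x[iobs[k]]
    drop(cbind(1, xi, xi^2, xi^3) %*% stats::coef(fm))
  }, 0)
}

#' Cross-validation index
#'
#' `CV = 1 - MSEP / (sum_ij (y_ij - ybar_{i,-j})^2 / n)`, where
#' `ybar_{i,-j}` is the mean apparent methylation at AMP `i` over all CpGs
#' except `j` (same missing-cell mask as the numerator).  Defined for the
#' `"cell"` and `"cpg"` scenarios only; a negative value favours the
#' nonparametric leave-one-CpG-out mean predictor.
#'
#' @inheritParams msep
#' @return CV-index, at most 1 (equal to 1 iff MSEP is 0).
#' @export
cvIndex <- function(data, method = c("bayes", "cpr"),
                    scenario = c("cell", "cpg"),
                    spec = makeModelSpec("M2"),
                    engine = engineOptions(chains = 1L, iter = 400L, warmup = 150L)) {
  scenario <- match.arg(scenario)
  y <- data@apparent
  if (ncol(y) < 2L) stop("the leave-one-CpG-out mean needs at least 2 CpGs")
  num <- as.numeric(msep(data, method, scenario, spec, engine))
  obs <- which(!is.na(y))
  l <- nrow(y)
  ss <- 0
  for (cell in obs) {
    i <- ((cell - 1L) %% l) + 1L
    j <- ((cell - 1L) %/% l) + 1L
    others <- y[i, -j]
    ybar <- mean(others, na.rm = TRUE)
    ss <- ss + (y[cell] - ybar)^2
  }
  1 - num / (ss / length(obs))
}

#' Distance-weighted flanking prediction for an excluded CpG
#'
#' Predicts the apparent methylation of an excluded CpG at every AMP level
#' from the CPR curves of its two immediate flanking CpGs, weighted by
#' linear interpolation in genomic distance: with flank distances `d_L` and
#' `d_R`, the left flank has weight `d_R / (d_L + d_R)` (the closer flank
#' weighs more).  Boundary CpGs use the single nearest flank.
#'
#' @param cpr a [CPRFit-class] on the full design.
#' @param design the [CalibrationDesign-class].
#' @param excludedCpg index of the excluded CpG.
#' @return Numeric vector of predictions, one per AMP level.
#' @export
flankingWeightedPrediction <- function(cpr, design, excludedCpg) {
  m <- length(design@cpgPositions)
  if (m < 2L) stop("flanking prediction needs at least 2 CpGs")
  j <- excludedCpg
  x <- design@ampLevels
  p <- design@cpgPositions
  if (j == 1L) return(cprPredict(cpr, 2L, x))
  if (j == m) return(cprPredict(cpr, m - 1L, x))
  dl <- p[j] - p[j - 1L]
  dr <- p[j + 1L] - p[j]
  wl <- dr / (dl + dr)
  wl * cprPredict(cpr, j - 1L, x) + (1 - wl) * cprPredict(cpr, j + 1L, x)
}
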