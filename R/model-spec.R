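#' Default prior configuration
#'
#' Priors of the calibration models: diffuse normals on the polynomial
#' coefficients, Gamma priors on the AMP/CpG effect precisions, an
#' inverse-Gamma prior on the RW1 variance scale, a Wishart prior on the
#' precision matrix of the (intercept, slope) pairs, and a near-flat
#' inverse-Gamma prior on the residual variance.
#'
#' * `betaVariance` (1e3): prior variance of the non-intercept polynomial
#'   coefficients (raw percent scale).
#' * `interceptVariance` (1e6): diffuse-normal variance of the intercept.
#' * `tauGamma`, `upsilonGamma` (shape 1, rate 0.1): Gamma priors on the AMP
#'   and CpG effect precisions (prior mean 10, variance 100).
#' * `rhoGamma` (shape 1, rate 0.1): Gamma prior on the RW1 *precision*
#'   (equivalently inverse-Gamma on the variance scale `rho`).
#' * `wishartDf` (4) and `wishartScale` (identity): `Sigma ~ W2(r, R)` on the
#'   precision of the (intercept, slope) pairs, parameterized so that
#'   `E(Sigma^-1) = R / (r - 3)`; `r > 3` is required for this mean to exist.
#' * `sigma2InvGamma` (shape 1e-10, rate 0.001): residual-variance prior,
#'   implemented as a Gamma(shape, rate) prior on the residual precision;
#'   set `sigma2Parameterization = "scale"` to read the second element as the
#'   inverse-Gamma scale instead (the two coincide here).
#'
#' @return Named list of hyperparameters.
#' @export
defaultPriors <- function() {
  list(betaVariance = 1e3,
       interceptVariance = 1e6,
       tauGamma = c(shape = 1, rate = 0.1),
       upsilonGamma = c(shape = 1, rate = 0.1),
       rhoGamma = c(shape = 1, rate = 0.1),
       wishartDf = 4,
       wishartScale = diag(2),
       sigma2InvGamma = c(shape = 1e-10, rate = 0.001),
       sigma2Parameterization = "rate")
}

.validate_priors <- function(p) {
  msg <- character()
  for (nm in c("betaVariance", "interceptVariance")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", nm))
  }
  for (nm in c("tauGamma", "upsilonGamma", "rhoGamma", "sigma2InvGamma")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0))
      msg <- c(msg, sprintf("%s must be two positive numbers (shape, rate)", nm))
  }
  if (!is.numeric(p$wishartDf) || length(p$wishartDf) != 1L || p$wishartDf <= 3)
    msg <- c(msg, "wishartDf must exceed 3 (dimension 2 plus 1) for E(Sigma^-1) = R/(r-3) to exist")
  R <- p$wishartScale
  if (!is.matrix(R) || !all(dim(R) == 2L) || abs(R[1L, 2L] - R[2L, 1L]) > 1e-12 ||
      any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msg <- c(msg, "wishartScale must be a symmetric positive-definite 2x2 matrix")
  if (!identical(p$sigma2Parameterization, "rate") &&
      !identical(p$sigma2Parameterization, "scale"))
    msg <- c(msg, "sigma2Parameterization must be 'rate' or 'scale'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' Create a model specification
#'
#' @param model one of `"M1"` (AMP effects), `"M2"` (+ crossed CpG effects),
#'   `"M3"` (+ RW1 latent field over CpG positions), `"M4"` (+ correlated
#'   CpG intercepts and slopes).
#' @param ... named prior overrides, see [defaultPriors()].
#' @param rw1FirstState `"sumtozero"` (intrinsic RW1, default) or
#'   `"anchored"` (first increment anchored at position 0).
#' @return A [ModelSpec-class].
#' @examples
#' makeModelSpec("M2")
#' makeModelSpec("M1", betaVariance = 10)
#' @export
makeModelSpec <- function(model, ..., rw1FirstState = c("sumtozero", "anchored")) {
  model <- as.character(model)
  if (length(model) != 1L || !model %in% c("M1", "M2", "M3", "M4"))
    stop("unknown model id: ", paste(model, collapse = ", "),
         " (expected one of M1, M2, M3, M4)")
  priors <- defaultPriors()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(priors))
  if (length(unknown))
    stop("unknown prior setting(s): ", paste(unknown, collapse = ", "))
  priors[names(overrides)] <- overrides
  pv <- .validate_priors(priors)
  if (!isTRUE(pv)) stop(pv)
  new("ModelSpec", model = model, priors = priors, sumToZero = TRUE,
      rw1FirstState = match.arg(rw1FirstState))
}

#' Parameter counts of the calibration models
#'
#' All four models have 5 main-effect parameters (4 polynomial coefficients
#' and the error variance).  The number of random-effects coefficients is
#' `l + 1` for M1, `l + m + 2` for M2 and M3, and `l + 2m + 4` for M4, versus
#' `5m` for the per-CpG cubic polynomial baseline.
#'
#' @param model model identifier.
#' @param l number of AMP levels.
#' @param m number of CpGs.
#' @return Named numeric vector `c(main = 5, random = ...)`.
#' @examples
#' parameterCount("M1", l = 5, m = 17)  # c(main = 5, random = 6)
#' @export
parameterCount <- function(model, l, m) {
  if (!model %in% c("M1", "M2", "M3", "M4")) stop("unknown model id: ", model)
  if (length(l) != 1L || length(m) != 1L || is.na(l) || is.na(m) || l < 1 || m < 1)
    stop("l and m must be positive counts")
  random <- switch(model, M1 = l + 1, M2 = l + m + 2, M3 = l + m + 2,
                   M4 = l + 2 * m + 4)
  c(main = 5, random = random)
}

#' Marginal variance of an observation under each model
#'
#' Closed-form variance of `Y_ij` given the variance components, integrating
#' over the random effects:
#' `sigma^2 + tau^-1` (M1), `+ upsilon^-1` (M2),
#' `+ rho * sum_{h<=j} |p_h - p_{h-1}|` with `p_0 = 0` (M3), and
#' `+ V11 + x^2 V22 + 2 x V12` with `V = Sigma^-1` the covariance of the
#' (intercept, slope) pairs (M4).
#'
#' @param model model identifier.
#' @param params a [TruthParams-class] (`Sigma` is interpreted as the effect
#'   *covariance* `Sigma^-1` of the prior notation).
#' @param x AMP value in percent (M4 only).
#' @param j CpG index (M3 only).
#' @param positions CpG positions (M3 only).
#' @return Variance (percent^2).
#' @export
marginalVariance <- function(model, params, x = 0, j = 1L, positions = NULL) {
  base <- params@sigma2 + 1 / params@tau
  switch(model,
    M1 = base,
    M2 = base + 1 / params@upsilon,
    M3 = {
      if (is.null(positions)) stop("M3 marginal variance needs CpG positions")
      p <- c(0, positions)
      base + params@rho * sum(abs(diff(p))[seq_len(j)])
    },
    M4 = {
      V <- params@Sigma
      if (abs(det(V)) < .Machine$double.eps) stop("singular effect covariance")
      base + V[1L, 1L] + x^2 * V[2L, 2L] + 2 * x * V[1L, 2L]
    },
    stop("unknown model id: ", model))
}

#' Marginal covariance between two observations
#'
#' For M4, the covariance between observations at distinct AMP/CpG pairs:
#' `tau^-1 + V11 + x1 x2 V22 + (x1 + x2) V12` with `V` the effect covariance.
#' For M1 only the shared AMP-effect structure remains and the covariance at
#' distinct AMPs/CpGs is `tau^-1` under the same decomposition logic.
#'
#' @inheritParams marginalVariance
#' @param x1,x2 the two AMP values (percent).
#' @return Covariance (percent^2).
#' @export
marginalCovariance <- function(model, params, x1, x2) {
  tinv <- 1 / params@tau
  switch(model,
    M1 = tinv,
    M4 = {
      V <- params@Sigma
      tinv + V[1L, 1L] + x1 * x2 * V[2L, 2L] + (x1 + x2) * V[1L, 2L]
    },
    stop("marginal covariance is defined for models M1 and M4"))
}
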