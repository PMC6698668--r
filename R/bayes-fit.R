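#' Engine options for the blocked Gibbs sampler
#'
#' @param chains number of independent chains (run sequentially from one
#'   seeded RNG stream).
#' @param iter post-warmup iterations per chain.
#' @param warmup warmup (discarded) iterations per chain.
#' @param seed integer seed; the same seed reproduces the fit exactly.
#' @param fixed named list of variance components to hold fixed instead of
#'   sampling (`sigma2`, `tau`, `upsilon`, `rho`, `SigmaPrec`); used for
#'   conjugate-reduction checks.
#' @param rhatThreshold split-Rhat convergence gate (default 1.05).
#' @param onNonconvergence `"warn"` (default), `"error"` or `"silent"` when
#'   the gate is exceeded.
#' @return Named list of engine options.
#' @export
engineOptions <- function(chains = 2L, iter = 1000L, warmup = 500L, seed = 1L,
                          fixed = list(),
                          rhatThreshold = 1.05,
                          onNonconvergence = c("warn", "error", "silent")) {
  stopifnot(chains >= 1L, iter >= 10L, warmup >= 0L)
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup), seed = as.integer(seed), fixed = fixed,
       rhatThreshold = rhatThreshold,
       onNonconvergence = match.arg(onNonconvergence))
}

# Assemble the fixed design information shared by all Gibbs iterations.
.fit_layout <- function(data, spec) {
  d <- data@design
  y <- data@apparent
  l <- length(d@ampLevels); m <- length(d@cpgPositions)
  obs <- which(!is.na(y))                       # column-major over l x m grid
  iobs <- ((obs - 1L) %% l) + 1L
  jobs <- ((obs - 1L) %/% l) + 1L
  xobs <- d@ampLevels[iobs]
  if (length(unique(xobs)) < 4L)
    stop("at least 4 distinct AMP levels with data are required to identify the cubic trend")
  Cl <- .sumzero_basis(l)
  Cm <- .sumzero_basis(m)
  model <- spec@model
  anchored <- model == "M3" && spec@rw1FirstState == "anchored"

  # Scaled polynomial basis t = x/100 keeps the location block well
  # conditioned; priors are transported exactly (var(b_k) = var(beta_k)*100^2k).
  make_X <- function(ii, jj, xx) {
    tt <- xx / 100
    blocks <- list(fixed = .poly_basis(tt), amp = Cl[ii, , drop = FALSE])
    if (model == "M2") blocks$cpg <- Cm[jj, , drop = FALSE]
    if (model == "M3") blocks$lgf <- if (anchored) diag(m)[jj, , drop = FALSE]
                                     else Cm[jj, , drop = FALSE]
    if (model == "M4") {
      blocks$cpg <- Cm[jj, , drop = FALSE]
      blocks$slope <- Cm[jj, , drop = FALSE] * xx
    }
    blocks
  }
  blocks <- make_X(iobs, jobs, xobs)
  sizes <- vapply(blocks, ncol, 0L)
  idx <- split(seq_len(sum(sizes)), rep(names(sizes), sizes))[names(sizes)]
  X <- do.call(cbind, blocks)

  iall <- rep(seq_len(l), m); jall <- rep(seq_len(m), each = l)
  Xall <- do.call(cbind, make_X(iall, jall, d@ampLevels[iall]))

  pr <- spec@priors
  pf <- c(1 / pr$interceptVariance, 1 / (pr$betaVariance * 100^(2 * (1:3))))
  K <- .rw1_structure(d@cpgPositions)
  if (anchored) K[1L, 1L] <- K[1L, 1L] + 1 / d@cpgPositions[1L]
  Klat <- if (model == "M3") {
    if (anchored) K else crossprod(Cm, K %*% Cm)
  } else NULL

  list(y = as.numeric(y[obs]), n = length(obs), l = l, m = m,
       obs = obs, iobs = iobs, jobs = jobs, xobs = xobs,
       X = X, XtX = crossprod(X), Xty = crossprod(X, as.numeric(y[obs])),
       Xall = Xall, idx = idx, sizes = sizes, Cl = Cl, Cm = Cm,
       Klat = Klat, rankK = if (anchored) m else m - 1L,
       pf = pf, model = model, anchored = anchored, priors = pr)
}

# Prior precision of the location block given current variance state.
.prior_precision <- function(lay, st) {
  p <- sum(lay$sizes)
  P0 <- matrix(0, p, p)
  diag(P0)[lay$idx$fixed] <- lay$pf
  diag(P0)[lay$idx$amp] <- st$tau
  if (!is.null(lay$idx$cpg) && lay$model == "M2")
    diag(P0)[lay$idx$cpg] <- st$upsilon
  if (!is.null(lay$idx$lgf))
    P0[lay$idx$lgf, lay$idx$lgf] <- lay$Klat / st$rho
  if (!is.null(lay$idx$slope)) {
    S <- st$SigmaPrec
    ic <- lay$idx$cpg; is <- lay$idx$slope
    diag(P0)[ic] <- S[1L, 1L]
    diag(P0)[is] <- S[2L, 2L]
    P0[cbind(ic, is)] <- S[1L, 2L]
    P0[cbind(is, ic)] <- S[1L, 2L]
  }
  P0
}

.run_gibbs <- function(lay, spec, engine) {
  pr <- lay$priors
  fx <- engine$fixed
  p <- sum(lay$sizes)
  ndraw <- engine$chains * engine$iter
  theta_store <- matrix(0, ndraw, p)
  hyper_store <- matrix(0, ndraw, 7L)  # sigma2 tau upsilon rho V11 V22 V12
  colnames(hyper_store) <- c("sigma2", "tau", "upsilon", "rho", "V11", "V22", "V12")
  chain_id <- rep(seq_len(engine$chains), each = engine$iter)
  a_s <- pr$sigma2InvGamma[1L]; b_s <- pr$sigma2InvGamma[2L]
  a_t <- pr$tauGamma[1L]; b_t <- pr$tauGamma[2L]
  a_u <- pr$upsilonGamma[1L]; b_u <- pr$upsilonGamma[2L]
  a_r <- pr$rhoGamma[1L]; b_r <- pr$rhoGamma[2L]
  Rw <- pr$wishartScale; r0 <- pr$wishartDf
  yv <- lay$y; n <- lay$n
  row <- 0L
  for (ch in seq_len(engine$chains)) {
    st <- list(sigma2 = fx$sigma2 %||% max(stats::var(yv), 1e-3),
               tau = fx$tau %||% 1,
               upsilon = fx$upsilon %||% 1,
               rho = fx$rho %||% 1,
               SigmaPrec = fx$SigmaPrec %||% diag(2))
    for (it in seq_len(engine$warmup + engine$iter)) {
      P <- lay$XtX / st$sigma2 + .prior_precision(lay, st)
      U <- chol(P)
      mu <- backsolve(U, backsolve(U, lay$Xty / st$sigma2, transpose = TRUE))
      theta <- drop(mu + backsolve(U, stats::rnorm(p)))
      resid <- yv - drop(lay$X %*% theta)
      if (is.null(fx$sigma2))
        st$sigma2 <- 1 / stats::rgamma(1L, a_s + n / 2, rate = b_s + sum(resid^2) / 2)
      za <- theta[lay$idx$amp]
      if (is.null(fx$tau))
        st$tau <- stats::rgamma(1L, a_t + length(za) / 2, rate = b_t + sum(za^2) / 2)
      if (lay$model == "M2" && is.null(fx$upsilon)) {
        zc <- theta[lay$idx$cpg]
        st$upsilon <- stats::rgamma(1L, a_u + length(zc) / 2, rate = b_u + sum(zc^2) / 2)
      }
      if (lay$model == "M3" && is.null(fx$rho)) {
        zl <- theta[lay$idx$lgf]
        quad <- drop(crossprod(zl, lay$Klat %*% zl))
        st$rho <- 1 / stats::rgamma(1L, a_r + lay$rankK / 2, rate = b_r + quad / 2)
      }
      if (lay$model == "M4" && is.null(fx$SigmaPrec)) {
        W <- cbind(theta[lay$idx$cpg], theta[lay$idx$slope])
        Spost <- solve(Rw + crossprod(W))
        Spost <- (Spost + t(Spost)) / 2
        st$SigmaPrec <- stats::rWishart(1L, r0 + nrow(W), Spost)[, , 1L]
      }
      if (it > engine$warmup) {
        row <- row + 1L
        theta_store[row, ] <- theta
        V <- tryCatch(solve(st$SigmaPrec), error = function(e) matrix(NA_real_, 2L, 2L))
        hyper_store[row, ] <- c(st$sigma2, st$tau, st$upsilon, st$rho,
                                V[1L, 1L], V[2L, 2L], V[1L, 2L])
      }
    }
  }
  list(theta = theta_store, hyper = hyper_store, chain = chain_id)
}

#' Fit a calibration model by blocked Gibbs sampling
#'
#' Fits one of the four Bayesian mixed additive calibration models to a
#' standard-control dataset.  The location parameters (polynomial
#' coefficients and all random effects, expressed in sum-to-zero centered
#' bases) are drawn jointly from their exact Gaussian full conditional; the
#' variance components follow conjugate Gamma / inverse-Gamma / Wishart
#' updates.  Missing cells are simply excluded from the likelihood.
#'
#' @param data a [CalibrationData-class]; at least 4 distinct AMP levels are
#'   required.
#' @param spec a [ModelSpec-class].
#' @param engine options from [engineOptions()].
#' @return A [CalibrationFit-class].
#' @examples
#' des <- calibrationDesign(c(0, 25, 50, 75, 100), c(10, 20, 40))
#' dat <- simulateCalibration(des, truthParams(sigma2 = 1), "M1", seed = 7)$data
#' fit <- fitCalibration(dat, makeModelSpec("M1"),
#'                       engineOptions(chains = 1, iter = 200, warmup = 100))
#' @export
fitCalibration <- function(data, spec = makeModelSpec("M2"),
                           engine = engineOptions()) {
  stopifnot(is(data, "CalibrationData"), is(spec, "ModelSpec"))
  validObject(data)
  lay <- .fit_layout(data, spec)
  res <- .with_seed(engine$seed, {
    r <- .run_gibbs(lay, spec, engine)
    r$noise <- stats::rnorm(nrow(r$theta) * lay$l * lay$m)
    r
  })
  .assemble_fit(data, spec, engine, lay, res)
}

.assemble_fit <- function(data, spec, engine, lay, res) {
  theta <- res$theta; hyper <- res$hyper
  l <- lay$l; m <- lay$m
  scale_back <- c(1, 100^-(1:3))
  beta <- sweep(theta[, lay$idx$fixed, drop = FALSE], 2L, scale_back, `*`)
  colnames(beta) <- paste0("beta", 0:3)
  amp <- theta[, lay$idx$amp, drop = FALSE] %*% t(lay$Cl)
  cpg <- if (!is.null(lay$idx$cpg))
    theta[, lay$idx$cpg, drop = FALSE] %*% t(lay$Cm) else NULL
  lgf <- if (!is.null(lay$idx$lgf)) {
    if (lay$anchored) theta[, lay$idx$lgf, drop = FALSE]
    else theta[, lay$idx$lgf, drop = FALSE] %*% t(lay$Cm)
  } else NULL
  slope <- if (!is.null(lay$idx$slope))
    theta[, lay$idx$slope, drop = FALSE] %*% t(lay$Cm) else NULL

  lp <- tcrossprod(theta, lay$Xall)            # draws x (l*m), column-major grid
  yrep <- lp + matrix(res$noise, nrow(lp), ncol(lp)) * sqrt(hyper[, "sigma2"])

  draws <- list(beta = beta, amp = amp, cpg = cpg, lgf = lgf, slope = slope,
                sigma2 = hyper[, "sigma2", drop = FALSE],
                tau = hyper[, "tau", drop = FALSE],
                upsilon = if (lay$model == "M2") hyper[, "upsilon", drop = FALSE] else NULL,
                rho = if (lay$model == "M3") hyper[, "rho", drop = FALSE] else NULL,
                SigmaInv = if (lay$model == "M4") hyper[, c("V11", "V22", "V12")] else NULL,
                lp = lp, yrep = yrep)

  monitored <- cbind(beta,
                     logsigma2 = log(hyper[, "sigma2"]),
                     logtau = log(hyper[, "tau"]))
  if (lay$model == "M2") monitored <- cbind(monitored, logupsilon = log(hyper[, "upsilon"]))
  if (lay$model == "M3") monitored <- cbind(monitored, logrho = log(hyper[, "rho"]))
  if (lay$model == "M4") monitored <- cbind(monitored, logV11 = log(hyper[, "V11"]),
                                            logV22 = log(hyper[, "V22"]))
  rhat <- apply(monitored, 2L, .split_rhat, chain = res$chain)
  convd <- all(is.na(rhat) | rhat < engine$rhatThreshold) && !anyNA(monitored)
  if (!convd) {
    msg <- sprintf("convergence gate failed: max split-Rhat %.3f (threshold %.3f)",
                   max(rhat, na.rm = TRUE), engine$rhatThreshold)
    if (engine$onNonconvergence == "error") stop(msg)
    if (engine$onNonconvergence == "warn") warning(msg)
  }

  summ <- list(beta = .quantile_summary(beta), amp = .quantile_summary(amp),
               sigma2 = .quantile_summary(draws$sigma2),
               tau = .quantile_summary(draws$tau))
  for (blk in c("cpg", "lgf", "slope", "upsilon", "rho", "SigmaInv"))
    if (!is.null(draws[[blk]])) summ[[blk]] <- .quantile_summary(draws[[blk]])

  fitted <- matrix(.clip01(colMeans(lp)), l, m)
  dimnames(fitted) <- dimnames(data@apparent)

  # Conditional-deviance DIC: deviance given the latent effects.
  obs <- lay$obs
  s2 <- hyper[, "sigma2"]
  rss_d <- rowSums((lp[, obs, drop = FALSE] -
                    matrix(lay$y, nrow(lp), lay$n, byrow = TRUE))^2)
  dev_d <- lay$n * log(2 * pi * s2) + rss_d / s2
  lp_bar <- colMeans(lp[, obs, drop = FALSE])
  s2_bar <- mean(s2)
  Dhat <- lay$n * log(2 * pi * s2_bar) + sum((lay$y - lp_bar)^2) / s2_bar
  Dbar <- mean(dev_d)
  pD <- Dbar - Dhat
  dicv <- Dbar + pD

  new("CalibrationFit", model = lay$model, spec = spec, data = data,
      draws = draws, summary = summ, fitted = fitted,
      dic = dicv, dicInfo = list(Dbar = Dbar, Dhat = Dhat, pD = pD),
      diagnostics = list(rhat = rhat, converged = convd, seed = engine$seed),
      engine = engine)
}

#' Deviance information criterion of a fit
#'
#' Conditional-deviance DIC (`Dbar + pD`, conditioning on the latent
#' effects), as stored on the fit.
#'
#' @param fit a [CalibrationFit-class].
#' @return Named list with `DIC`, `Dbar`, `Dhat`, `pD`.
#' @export
dicComponents <- function(fit) {
  stopifnot(is(fit, "CalibrationFit"))
  c(list(DIC = fit@dic), fit@dicInfo)
}

#' Select a model by DIC
#'
#' Picks the model with minimal DIC; ties within `tieTol` are broken toward
#' the simpler model (M1 < M2 < M3 < M4).
#'
#' @param dics named numeric vector of DIC values (names among M1..M4).
#' @param tieTol tie tolerance.
#' @return The selected model id.
#' @examples
#' selectModel(c(M1 = 173.55, M2 = 172.46, M3 = 167.87, M4 = 164.68))  # "M4"
#' @export
selectModel <- function(dics, tieTol = 0) {
  if (length(dics) == 0L) stop("empty DIC map")
  if (is.null(names(dics)) || !all(names(dics) %in% c("M1", "M2", "M3", "M4")))
    stop("DIC values must be named with model ids M1..M4")
  cand <- names(dics)[dics <= min(dics) + tieTol]
  cand[order(match(cand, c("M1", "M2", "M3", "M4")))][1L]
}

#' Posterior prediction at a design cell
#'
#' Posterior mean (sum of the component posterior means) and quantile band
#' of the linear predictor at AMP level `i`, CpG `j`, both clipped to
#' \[0,100\].  The default band comes from joint posterior draws of the full
#' linear predictor; `additive = TRUE` instead sums the componentwise
#' quantiles (the literal additive-quantile formula, which ignores posterior
#' dependence between components).
#'
#' @param fit a [CalibrationFit-class].
#' @param i AMP index; @param j CpG index.
#' @param additive use the additive-quantile mode.
#' @return Named numeric: `mean`, `q2.5`, `q25`, `q50`, `q75`, `q97.5`.
#' @export
posteriorPredict <- function(fit, i, j, additive = FALSE) {
  l <- nrow(fit@fitted); m <- ncol(fit@fitted)
  if (i < 1L || i > l || j < 1L || j > m) stop("index out of range")
  cell <- (j - 1L) * l + i
  mn <- .cell_mean(fit, i, j)
  if (!additive) {
    q <- stats::quantile(fit@draws$lp[, cell], c(.025, .25, .5, .75, .975),
                         names = FALSE)
  } else {
    x <- drop(.poly_basis(fit@data@design@ampLevels[i]))
    qs <- function(v) stats::quantile(v, c(.025, .25, .5, .75, .975), names = FALSE)
    q <- drop(apply(fit@draws$beta, 2L, qs) %*% x) +
      qs(fit@draws$amp[, i]) +
      .cj_quantiles(fit, j, fit@data@design@ampLevels[i], qs)
  }
  out <- c(mean = .clip01(mn), stats::setNames(.clip01(q),
           c("q2.5", "q25", "q50", "q75", "q97.5")))
  out
}

.cell_mean <- function(fit, i, j) {
  x <- fit@data@design@ampLevels[i]
  mn <- drop(.poly_basis(x) %*% colMeans(fit@draws$beta)) + mean(fit@draws$amp[, i])
  mn + .cj_mean(fit, j, x)
}

.cj_mean <- function(fit, j, x) {
  out <- 0
  if (!is.null(fit@draws$cpg)) out <- out + mean(fit@draws$cpg[, j])
  if (!is.null(fit@draws$lgf)) out <- out + mean(fit@draws$lgf[, j])
  if (!is.null(fit@draws$slope)) out <- out + mean(fit@draws$slope[, j]) * x
  out
}

.cj_quantiles <- function(fit, j, x, qs) {
  out <- 0
  if (!is.null(fit@draws$cpg)) out <- out + qs(fit@draws$cpg[, j])
  if (!is.null(fit@draws$lgf)) out <- out + qs(fit@draws$lgf[, j])
  if (!is.null(fit@draws$slope)) out <- out + qs(fit@draws$slope[, j]) * x
  out
}

#' Impute missing calibration cells
#'
#' Missing cells (including wholly removed CpGs) are imputed from the terms
#' common to all CpGs: posterior-mean polynomial plus the posterior mean of
#' the AMP random effect at that level, clipped to \[0,100\].
#'
#' @param fit a [CalibrationFit-class].
#' @return data.frame with one row per missing cell (`amp_index`,
#'   `cpg_index`, `amp`, `cpg_pos`, `imputed`); zero rows when nothing is
#'   missing.
#' @export
imputeMissing <- function(fit) {
  y <- fit@data@apparent
  d <- fit@data@design
  miss <- which(is.na(y), arr.ind = TRUE)
  if (nrow(miss) == 0L)
    return(data.frame(amp_index = integer(), cpg_index = integer(),
                      amp = numeric(), cpg_pos = numeric(), imputed = numeric()))
  bhat <- colMeans(fit@draws$beta)
  eta <- colMeans(fit@draws$amp)
  x <- d@ampLevels[miss[, 1L]]
  val <- .clip01(drop(.poly_basis(x) %*% bhat) + eta[miss[, 1L]])
  data.frame(amp_index = miss[, 1L], cpg_index = miss[, 2L], amp = x,
             cpg_pos = d@cpgPositions[miss[, 2L]], imputed = val,
             row.names = NULL)
}

#' Posterior-predictive outlier fences
#'
#' For every observed cell, the first and third quartile of the posterior
#' predictive distribution (linear predictor plus residual noise) define
#' Tukey fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; observations outside the
#' fences are flagged.
#'
#' @param fit a [CalibrationFit-class].
#' @return data.frame per observed cell: `amp_index`, `cpg_index`, `amp`,
#'   `cpg_pos`, `observed`, `q1`, `q3`, `lower`, `upper`, `flag`.
#' @export
flagOutliers <- function(fit) {
  y <- fit@data@apparent
  d <- fit@data@design
  l <- nrow(y)
  obs <- which(!is.na(y))
  q13 <- apply(fit@draws$yrep[, obs, drop = FALSE], 2L, stats::quantile,
               probs = c(.25, .75), names = FALSE)
  iqr <- q13[2L, ] - q13[1L, ]
  if (any(iqr == 0))
    warning("degenerate predictive distribution (zero IQR) for some cells; any deviation is flagged there")
  lower <- q13[1L, ] - 1.5 * iqr
  upper <- q13[2L, ] + 1.5 * iqr
  yv <- y[obs]
  data.frame(amp_index = ((obs - 1L) %% l) + 1L,
             cpg_index = ((obs - 1L) %/% l) + 1L,
             amp = d@ampLevels[((obs - 1L) %% l) + 1L],
             cpg_pos = d@cpgPositions[((obs - 1L) %/% l) + 1L],
             observed = yv, q1 = q13[1L, ], q3 = q13[2L, ],
             lower = lower, upper = upper,
             flag = yv < lower | yv > upper, row.names = NULL)
}
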