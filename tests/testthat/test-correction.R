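test_that("the AMP-effect spline interpolates its knots and matches a tridiagonal oracle", {
  kx <- c(0, 25, 50, 75, 100)
  # zero knots give the zero function
  f0 <- interpolateAmpEffects(list(knotsX = kx, knotsEta = rep(0, 5)))
  expect_equal(f0(seq(0, 100, by = 7)), rep(0, 15))
  # exact interpolation and agreement with an independent natural-cubic solve
  for (seed in 1:5) {
    set.seed(seed)
    eta <- stats::rnorm(5, 0, 4)
    f <- interpolateAmpEffects(list(knotsX = kx, knotsEta = eta))
    expect_equal(f(kx), eta)
    xs <- seq(0, 100, by = 2.5)
    expect_equal(f(xs), oracle_natural_spline(kx, eta, xs), tolerance = 1e-10)
  }
  ke <- c(0, 5, 0, -5, 0)
  f <- interpolateAmpEffects(list(knotsX = kx, knotsEta = ke))
  expect_equal(f(12.5), oracle_natural_spline(kx, ke, 12.5))
  # no extrapolation outside the design range
  expect_error(f(101), "outside the knot range")
  expect_error(interpolateAmpEffects(list(knotsX = c(0, 0, 50), knotsEta = 1:3)),
               "duplicate")
})

test_that("curves compose the per-model offset C_j correctly", {
  des <- toy_design(m = 4L)
  sim <- simulateCalibration(des, truthParams(beta = c(8, 1, -0.004, 1e-5),
                                              sigma2 = 1, tau = 0.3), "M1",
                             seed = 3)
  f1 <- fitCalibration(sim$data, makeModelSpec("M1"), quiet_engine(seed = 1))
  c1 <- buildCurve(f1)
  expect_equal(c1@cpgEffects, rep(0, 4))
  expect_equal(c1@cpgSlopes, rep(0, 4))
  expect_equal(c1@lgf, rep(0, 4))
  # all CpGs share one curve under M1
  expect_equal(evalCurve(c1, 1L, c(10, 60)), evalCurve(c1, 4L, c(10, 60)))

  # M4 offset: C_j(x) = CpG_j + CpG*_j x, checked by direct evaluation
  sim4 <- simulateCalibration(des, truthParams(beta = c(8, 1, -0.004, 1e-5),
                                               sigma2 = 1, tau = 0.3,
                                               Sigma = diag(c(1, 1e-4))), "M4",
                              seed = 4)
  f4 <- fitCalibration(sim4$data, makeModelSpec("M4"), quiet_engine(seed = 1))
  nd <- nrow(f4@draws$beta)
  f4@draws$cpg <- matrix(rep(c(1, -1, 1, -1), each = nd), nd, 4)
  f4@draws$slope <- matrix(rep(c(0.02, -0.02, 0.02, -0.02), each = nd), nd, 4)
  c4 <- buildCurve(f4)
  base <- drop(cbind(1, 50, 50^2, 50^3) %*% c4@beta) +
    interpolateAmpEffects(list(knotsX = c4@knotsX, knotsEta = c4@knotsEta))(50)
  expect_equal(evalCurve(c4, 1L, 50) - base, 1 + 0.02 * 50)

  # a near-identity fit yields a near-identity monotone curve
  tri <- truthParams(beta = c(0, 1, 0, 0), sigma2 = 0.01, tau = 1e4,
                     ampEffects = rep(0, 5), cpgEffects = rep(0, 4))
  simi <- simulateCalibration(des, tri, "M2", seed = 5)
  ci <- buildCurve(fitCalibration(simi$data, makeModelSpec("M2"),
                                  quiet_engine(seed = 2, iter = 800)))
  expect_true(all(ci@monotone))
  xs <- seq(0, 100, by = 10)
  expect_true(max(abs(evalCurve(ci, 2L, xs) - xs)) < 1)
})

test_that("curve inversion recovers the forward map and matches grid search", {
  for (seed in 1:8) {
    cur <- random_monotone_curve(seed)
    g <- function(x) evalCurve(cur, 1L, x)
    # round trip on a coarse grid (where the forward value is in range)
    for (x in seq(0, 100, by = 5)) {
      y <- g(x)
      if (y >= 0 && y <= 100)
        expect_lt(abs(correctObservation(cur, 1L, y) - x), 1e-3 + 1e-6)
    }
    # agreement with exhaustive grid search
    set.seed(seed + 100)
    for (yobs in stats::runif(3, max(0, g(0)), min(100, g(100)))) {
      expect_lt(abs(correctObservation(cur, 1L, yobs) -
                    oracle_grid_invert(g, yobs)), 2e-3)
    }
    # monotone in the observed value
    ys <- sort(stats::runif(5, 0, 100))
    xs <- vapply(ys, function(y) correctObservation(cur, 1L, y), 0)
    expect_true(all(diff(xs) >= -1e-6))
  }
  cur <- biased_curve()
  expect_equal(correctObservation(cur, 3L, evalCurve(cur, 3L, 37.3)), 37.3,
               tolerance = 1e-3)
  # boundary optima clamp to the design range
  lowy <- max(0, evalCurve(cur, 2L, 0) - 5)
  expect_equal(correctObservation(cur, 2L, lowy), 0)
  expect_error(correctObservation(cur, 1L, 120), "\\[0,100\\]")
})

test_that("sample correction averages non-missing CpGs and round-trips a cohort", {
  ident <- new("CalibrationCurve", model = "M1", beta = c(0, 1, 0, 0),
               knotsX = c(0, 25, 50, 75, 100), knotsEta = rep(0, 5),
               cpgPositions = c(10, 20, 30), cpgEffects = rep(0, 3),
               cpgSlopes = rep(0, 3), lgf = rep(0, 3), monotone = rep(TRUE, 3))
  samp <- sampleData(matrix(c(10, 20, 30), 1), "control", c(10, 20, 30),
                     sampleIds = "c1")
  res <- correctSamples(ident, samp)
  expect_equal(res@table$corrected, c(10, 20, 30), tolerance = 1e-6)
  expect_equal(unname(correctedMeans(res)), 20, tolerance = 1e-6)

  samp2 <- sampleData(matrix(c(10, NA, 30), 1), "case", c(10, 20, 30))
  res2 <- correctSamples(ident, samp2)
  expect_equal(unname(correctedMeans(res2)), 20, tolerance = 1e-6)

  # zero-noise cohort through a biased curve is recovered exactly
  cur <- biased_curve()
  true <- matrix(seq(5, 95, length.out = 36), 3, 12)
  co <- simulateCohort(cur, true, rep("control", 3), noiseSd = 0, seed = 2)
  corr <- correctSamples(cur, co$samples)
  truth_long <- true[cbind(match(corr@table$id, co$samples@sampleIds),
                           match(corr@table$cpg_pos, cur@cpgPositions))]
  expect_lt(mean(abs(corr@table$corrected - truth_long)), 1e-2)
})

test_that("CPR fits per-CpG cubics by least squares", {
  des <- toy_design(m = 3L)
  x <- ampLevels(des)
  y <- cbind(2 + 0.9 * x + 0.0005 * x^2,
             5 + 0.8 * x - 0.002 * x^2 + 1e-5 * x^3,
             1 + 0.95 * x)
  cpr <- fitCPR(calibrationData(des, y))
  expect_equal(cpr@coef[, 1L], c(2, 0.9, 0.0005, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # coefficients equal an explicit normal-equations solve on noisy data
  set.seed(12)
  ynoise <- .5 + y * 0.9 + matrix(stats::rnorm(15), 5, 3)
  ynoise <- pmax(pmin(ynoise, 100), 0)
  cprn <- fitCPR(calibrationData(des, ynoise))
  for (j in 1:3)
    expect_equal(cprn@coef[, j], oracle_cpr_coef(x, ynoise[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  # the 5-point design leaves one residual degree of freedom per CpG
  expect_true(all(is.finite(cprn@sigma2)))

  ymiss <- y
  ymiss[1:2, 2L] <- NA
  expect_error(fitCPR(calibrationData(des, ymiss)), "fewer than 4")
})

test_that("CPR inversion matches an analytic root solver", {
  des <- toy_design(m = 2L)
  x <- ampLevels(des)
  ident <- fitCPR(calibrationData(des, cbind(x, x)))
  expect_equal(cprCorrect(ident, 1L, 45), 45, tolerance = 1e-4)

  coefs <- c(3, 1.2, -0.008, 4e-5)             # strictly increasing cubic
  y <- drop(cbind(1, x, x^2, x^3) %*% coefs)
  cpr <- fitCPR(calibrationData(des, cbind(y, y)))
  for (yobs in c(12, 47.5, 83)) {
    roots <- polyroot(c(coefs[1L] - yobs, coefs[2L], coefs[3L], coefs[4L]))
    real <- Re(roots[abs(Im(roots)) < 1e-8])
    real <- real[real >= -1e-6 & real <= 100 + 1e-6]
    expect_equal(cprCorrect(cpr, 1L, yobs), real[1L], tolerance = 1e-3)
  }
  # observations above the curve maximum clamp at 100
  top <- min(100, drop(cbind(1, 100, 1e4, 1e6) %*% coefs) + 5)
  expect_equal(cprCorrect(cpr, 1L, top), 100)
})

test_that("correcting biased calibration data moves per-AMP means toward the true AMPs", {
  cur <- biased_curve(m = 8L)
  des <- calibrationDesign(c(0, 25, 50, 75, 100), cur@cpgPositions)
  set.seed(44)
  y <- t(vapply(seq_len(8L), function(j)
    evalCurve(cur, j, ampLevels(des)), numeric(5))) + stats::rnorm(40, 0, 1)
  y <- pmax(pmin(t(y), 100), 0)                  # l x m apparent grid
  dat <- calibrationData(des, y)
  fit <- fitCalibration(dat, makeModelSpec("M2"), quiet_engine(seed = 3))
  curve <- buildCurve(fit)
  corrected <- vapply(seq_len(8L), function(j)
    vapply(seq_len(5L), function(i) correctObservation(curve, j, y[i, j]), 0),
    numeric(5))
  err_corr <- abs(rowMeans(corrected) - ampLevels(des))
  err_raw <- abs(rowMeans(y) - ampLevels(des))
  expect_lt(mean(err_corr), mean(err_raw))

  cprf <- fitCPR(dat)
  cpr_corr <- vapply(seq_len(8L), function(j)
    vapply(seq_len(5L), function(i) cprCorrect(cprf, j, y[i, j]), 0),
    numeric(5))
  expect_lt(mean(abs(rowMeans(cpr_corr) - ampLevels(des))), mean(err_raw))
})

test_that("curves serialize to JSON and back", {
  cur <- biased_curve()
  path <- withr::local_tempfile(fileext = ".json")
  curveToJSON(cur, path)
  got <- curveFromJSON(path)
  expect_equal(got@beta, cur@beta)
  expect_equal(got@knotsEta, cur@knotsEta)
  expect_equal(got@monotone, cur@monotone)
  xs <- seq(0, 100, by = 12.5)
  expect_equal(evalCurve(got, 3L, xs), evalCurve(cur, 3L, xs))
})
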