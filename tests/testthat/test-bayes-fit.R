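test_that("posterior means of beta match generalized least squares on the conjugate reduction", {
  # M1 with fixed tau and sigma2 and a near-flat beta prior is conjugate:
  # beta | y is Gaussian with the GLS mean under V = sigma2 I + (1/tau) ZCC'Z'
  des <- toy_design(m = 8L, span = c(10, 200))
  tr <- truthParams(beta = c(3, 1.2, -0.003, 8e-6), sigma2 = 2, tau = 0.25)
  sim <- simulateCalibration(des, tr, "M1", seed = 21)
  spec <- makeModelSpec("M1", betaVariance = 1e12, interceptVariance = 1e12)
  fit <- fitCalibration(sim$data, spec,
                        engineOptions(chains = 2, iter = 2000, warmup = 300,
                                      seed = 4, fixed = list(tau = 0.25, sigma2 = 2)))
  y <- as.numeric(apparentMeth(sim$data))
  l <- 5L; m <- 8L
  ii <- rep(seq_len(l), m)
  X <- cbind(1, ampLevels(des)[ii], ampLevels(des)[ii]^2, ampLevels(des)[ii]^3)
  Za <- diag(l)[ii, ]
  C <- qr.Q(qr(matrix(1, l, 1)), complete = TRUE)[, -1]
  V <- 2 * diag(l * m) + (1 / 0.25) * Za %*% tcrossprod(C) %*% t(Za)
  bhat <- drop(solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y)))
  bg <- colMeans(fit@draws$beta)
  expect_lt(sqrt(sum((bg - bhat)^2)) / sqrt(sum(bhat^2)), 0.01)
})

test_that("constant data yield a flat fit", {
  des <- toy_design(m = 6L)
  y <- matrix(40, 5, 6)
  dat <- calibrationData(des, y)
  fit <- fitCalibration(dat, makeModelSpec("M1"), quiet_engine(seed = 2, iter = 1000))
  expect_true(all(abs(fittedMeans(fit) - 40) < 0.1))
  expect_true(all(abs(colMeans(fit@draws$beta)[2:4] * c(1, 1, 1)) <
                  c(1e-2, 1e-2, 1e-2)))
})

test_that("fits are deterministic given the seed and respect missingness", {
  des <- toy_design(m = 6L)
  sim <- simulateCalibration(des, truthParams(beta = c(8, 1, -0.004, 1e-5),
                                              sigma2 = 2, tau = 0.3,
                                              upsilon = 0.3), "M2", seed = 5)
  f1 <- fitCalibration(sim$data, makeModelSpec("M2"), quiet_engine(seed = 7))
  f2 <- fitCalibration(sim$data, makeModelSpec("M2"), quiet_engine(seed = 7))
  expect_identical(dic(f1), dic(f2))
  expect_identical(f1@draws$beta, f2@draws$beta)

  # a wholly missing CpG is excluded from the likelihood but still imputable
  y <- apparentMeth(sim$data)
  y[, 3L] <- NA
  fmiss <- fitCalibration(calibrationData(des, y), makeModelSpec("M2"),
                          quiet_engine(seed = 7))
  expect_s4_class(fmiss, "CalibrationFit")
  imp <- imputeMissing(fmiss)
  expect_equal(nrow(imp), 5L)
  expect_true(all(imp$cpg_index == 3L))
  expect_true(all(imp$imputed >= 0 & imp$imputed <= 100))

  # fewer than 4 distinct AMP levels cannot identify the cubic
  des3 <- calibrationDesign(c(0, 50, 100), c(10, 20))
  expect_error(fitCalibration(calibrationData(des3, matrix(50, 3, 2)),
                              makeModelSpec("M1"), quiet_engine()),
               "4 distinct AMP")
})

test_that("sum-to-zero constraints and summary bounds hold", {
  des <- toy_design(m = 10L)
  sim <- simulateCalibration(des, truthParams(beta = c(8, 1, -0.004, 1e-5),
                                              sigma2 = 2, tau = 0.3,
                                              Sigma = diag(c(4, 4e-4))),
                             "M4", seed = 9)
  fit <- fitCalibration(sim$data, makeModelSpec("M4"), quiet_engine(seed = 3))
  expect_lt(abs(sum(colMeans(fit@draws$amp))), 1e-6)
  expect_lt(abs(sum(colMeans(fit@draws$cpg))), 1e-6)
  expect_lt(abs(sum(colMeans(fit@draws$slope))), 1e-6)
  expect_true(all(fittedMeans(fit) >= 0 & fittedMeans(fit) <= 100))
  for (cell in list(c(1L, 1L), c(3L, 5L), c(5L, 10L))) {
    pp <- posteriorPredict(fit, cell[1L], cell[2L])
    expect_lte(pp[["q2.5"]], pp[["q97.5"]])
    expect_lte(pp[["q2.5"]], pp[["mean"]])
    expect_lte(pp[["mean"]], pp[["q97.5"]])
    pa <- posteriorPredict(fit, cell[1L], cell[2L], additive = TRUE)
    expect_true(all(pa >= 0 & pa <= 100))
  }
  expect_error(posteriorPredict(fit, 6L, 1L), "out of range")
})

test_that("an identity design is predicted back and clipping applies at the boundary", {
  des <- toy_design(m = 5L)
  tr <- truthParams(beta = c(0, 1, 0, 0), sigma2 = 0.01, tau = 1e4,
                    ampEffects = rep(0, 5), cpgEffects = rep(0, 5))
  sim <- simulateCalibration(des, tr, "M2", seed = 30)
  fit <- fitCalibration(sim$data, makeModelSpec("M2"), quiet_engine(seed = 8, iter = 800))
  pp <- posteriorPredict(fit, 3L, 2L)            # AMP level 50
  expect_lt(abs(pp[["mean"]] - 50), 0.5)

  # data hugging the upper bound force clipped summaries, never values > 100
  dat <- calibrationData(toy_design(m = 4L), matrix(99.9, 5, 4))
  fhi <- fitCalibration(dat, makeModelSpec("M1"), quiet_engine(seed = 4))
  expect_true(all(fittedMeans(fhi) <= 100))
  expect_true(all(posteriorPredict(fhi, 5L, 1L) <= 100))
})

test_that("imputation evaluates the fixed-effects-plus-AMP rule exactly", {
  des <- toy_design(m = 4L)
  y <- apparentMeth(simulateCalibration(des, truthParams(sigma2 = 1), "M1",
                                        seed = 2)$data)
  y[3L, 2L] <- NA                               # missing cell at AMP 50
  fit <- fitCalibration(calibrationData(des, y), makeModelSpec("M1"),
                        quiet_engine(seed = 5))
  nd <- nrow(fit@draws$beta)
  fit@draws$beta <- matrix(rep(c(0, 1, 0, 0), each = nd), nd, 4)
  fit@draws$amp <- matrix(rep(c(-1, -1, 2, 0, 0), each = nd), nd, 5)
  imp <- imputeMissing(fit)
  expect_equal(imp$imputed, 0 + 1 * 50 + 2)      # = 52 at any missing CpG
})

test_that("DIC model selection follows the minimum with ties to the simpler model", {
  expect_equal(selectModel(c(M1 = 173.55, M2 = 172.46, M3 = 167.87, M4 = 164.68)),
               "M4")
  expect_equal(selectModel(c(M1 = 179.06, M2 = 180.42, M3 = 178.21, M4 = 180.82)),
               "M3")
  expect_equal(selectModel(c(M2 = 100, M4 = 100)), "M2")
  expect_equal(selectModel(c(M4 = 100, M3 = 100.4), tieTol = 0.5), "M3")
  expect_error(selectModel(numeric(0)), "empty")
  expect_error(selectModel(c(bad = 1)), "named")
})

test_that("a superfluous random effect inflates the effective parameter count", {
  des <- toy_design(m = 10L)
  wins <- 0L
  for (s in 1:6) {
    sim <- simulateCalibration(des, truthParams(beta = c(8, 1.1, -0.006, 2e-5),
                                                sigma2 = 2, tau = 0.25), "M1",
                               seed = 300 + s)
    f1 <- fitCalibration(sim$data, makeModelSpec("M1"), quiet_engine(seed = s))
    f2 <- fitCalibration(sim$data, makeModelSpec("M2"), quiet_engine(seed = s))
    wins <- wins + (f2@dicInfo$pD > f1@dicInfo$pD)
  }
  expect_gte(wins, 5L)
})

test_that("outlier fences implement the quartile rule on the posterior predictive", {
  des <- toy_design(m = 8L)
  sim <- simulateCalibration(des, truthParams(beta = c(8, 1.1, -0.006, 2e-5),
                                              sigma2 = 2, tau = 0.25,
                                              upsilon = 0.1), "M2", seed = 17)
  fit <- fitCalibration(sim$data, makeModelSpec("M2"), quiet_engine(seed = 6))
  fl <- flagOutliers(fit)
  expect_equal(fl$lower, fl$q1 - 1.5 * (fl$q3 - fl$q1))
  expect_equal(fl$upper, fl$q3 + 1.5 * (fl$q3 - fl$q1))
  expect_equal(fl$flag, fl$observed < fl$lower | fl$observed > fl$upper)

  # an observation sitting at the predictive median is never flagged
  cell <- 7L
  fit2 <- fit
  fit2@data@apparent[cell] <- stats::median(fit@draws$yrep[, cell])
  fl2 <- flagOutliers(fit2)
  i <- ((cell - 1L) %% 5L) + 1L; j <- ((cell - 1L) %/% 5L) + 1L
  expect_false(fl2$flag[fl2$amp_index == i & fl2$cpg_index == j])
})

test_that("the anchored RW1 variant fits and differs from the intrinsic default", {
  des <- toy_design(m = 8L)
  sim <- simulateCalibration(des, truthParams(beta = c(8, 1.1, -0.006, 2e-5),
                                              sigma2 = 2, tau = 0.25,
                                              rho = 0.1), "M3", seed = 23)
  fint <- fitCalibration(sim$data, makeModelSpec("M3"), quiet_engine(seed = 2))
  fanc <- fitCalibration(sim$data,
                         makeModelSpec("M3", rw1FirstState = "anchored"),
                         quiet_engine(seed = 2))
  expect_lt(abs(sum(colMeans(fint@draws$lgf))), 1e-6)
  expect_s4_class(fanc, "CalibrationFit")
  expect_true(all(fittedMeans(fanc) >= 0 & fittedMeans(fanc) <= 100))
})
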