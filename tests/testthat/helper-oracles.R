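# Independent oracles and small fixture builders used across the suite.

# Natural cubic spline by a direct tridiagonal solve for the second
# derivatives (M_1 = M_n = 0), independent of stats::splinefun.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  if (n == 2L) return(stats::approx(x, y, xout)$y)
  A <- matrix(0, n - 2L, n - 2L)
  rhs <- numeric(n - 2L)
  for (i in 2L:(n - 1L)) {
    k <- i - 1L
    if (k > 1L) A[k, k - 1L] <- h[i - 1L] / 6
    A[k, k] <- (h[i - 1L] + h[i]) / 3
    if (k < n - 2L) A[k, k + 1L] <- h[i] / 6
    rhs[k] <- (y[i + 1L] - y[i]) / h[i] - (y[i] - y[i - 1L]) / h[i - 1L]
  }
  M <- c(0, solve(A, rhs), 0)
  vapply(xout, function(t) {
    i <- max(1L, min(n - 1L, findInterval(t, x)))
    hh <- h[i]
    a <- (x[i + 1L] - t) / hh
    b <- (t - x[i]) / hh
    a * y[i] + b * y[i + 1L] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1L]) * hh^2 / 6
  }, 0)
}

# Per-CpG cubic least squares by explicit normal equations.
oracle_cpr_coef <- function(x, y) {
  X <- cbind(1, x, x^2, x^3)
  drop(solve(crossprod(X), crossprod(X, y)))
}

.clip01_test <- function(x) {
  x[x < 0] <- 0
  x[x > 100] <- 100
  x
}

# Exhaustive grid inversion of a forward map on [0,100].
oracle_grid_invert <- function(g, yobs, step = 1e-3) {
  grid <- seq(0, 100, by = step)
  grid[which.min((g(grid) - yobs)^2)]
}

toy_design <- function(l = 5L, m = 6L, span = c(101, 300)) {
  levels <- if (l == 5L) c(0, 25, 50, 75, 100) else seq(0, 100, length.out = l)
  calibrationDesign(levels, seq(span[1L], span[2L], length.out = m),
                    assayId = "toy")
}

quiet_engine <- function(seed = 1L, iter = 500L, warmup = 250L, chains = 1L) {
  engineOptions(chains = chains, iter = iter, warmup = warmup, seed = seed,
                onNonconvergence = "silent")
}

# A strictly increasing biased forward curve with non-trivial spline knots,
# used by correction round-trip and cohort experiments.
biased_curve <- function(m = 12L) {
  new("CalibrationCurve", model = "M2", beta = c(0, 2.2, -0.021, 7e-5),
      knotsX = c(0, 25, 50, 75, 100), knotsEta = c(0, 3, 2, -1, 0),
      cpgPositions = seq(101, 100 + m * 10, length.out = m),
      cpgEffects = rep_len(c(-1, 1), m), cpgSlopes = numeric(m),
      lgf = numeric(m), monotone = rep(TRUE, m))
}

# Random monotone single-CpG curves for inversion properties.
random_monotone_curve <- function(seed) {
  set.seed(seed)
  repeat {
    cand <- new("CalibrationCurve", model = "M2",
                beta = c(stats::runif(1, 0, 5), stats::runif(1, 0.5, 1.5),
                         stats::runif(1, -0.01, 0.01), stats::runif(1, -5e-5, 5e-5)),
                knotsX = c(0, 25, 50, 75, 100),
                knotsEta = stats::rnorm(5, 0, 2),
                cpgPositions = 150, cpgEffects = stats::rnorm(1, 0, 2),
                cpgSlopes = 0, lgf = 0, monotone = TRUE)
    g <- evalCurve(cand, 1L, seq(0, 100, by = 0.1))
    if (all(diff(g) > 0)) return(cand)
  }
}

write_calibration_fixture <- function(path, data, sep = "\t") {
  d <- designOf(data)
  y <- apparentMeth(data)
  grid <- expand.grid(i = seq_along(ampLevels(data)), j = seq_along(cpgPositions(data)))
  tab <- data.frame(assay_id = d@assayId, amp_percent = ampLevels(data)[grid$i],
                    cpg_pos = cpgPositions(data)[grid$j],
                    apparent_percent = y[cbind(grid$i, grid$j)])
  tab <- tab[!is.na(tab$apparent_percent), ]
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

write_sample_fixture <- function(path, samples, sep = "\t") {
  grid <- expand.grid(s = seq_along(samples@sampleIds),
                      j = seq_along(samples@cpgPositions))
  tab <- data.frame(sample_id = samples@sampleIds[grid$s],
                    group = as.character(samples@group)[grid$s],
                    cpg_pos = samples@cpgPositions[grid$j],
                    observed_percent = samples@observed[cbind(grid$s, grid$j)])
  tab <- tab[!is.na(tab$observed_percent), ]
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
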