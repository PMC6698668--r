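# Internal numerical helpers.

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 100] <- 100
  x
}

# Orthonormal basis of the sum-to-zero subspace of R^k: k x (k-1), columns
# orthonormal and orthogonal to the constant vector.  Effects a = C %*% z with
# z iid N(0, v) have an isotropic N(0, v) law restricted to {sum(a) = 0}, and
# ||a||^2 == ||z||^2.
.sumzero_basis <- function(k) {
  if (k < 2L) return(matrix(numeric(0), nrow = k, ncol = 0L))
  qr.Q(qr(matrix(1, k, 1L)), complete = TRUE)[, -1L, drop = FALSE]
}

# RW1 structure matrix K = D' W D over positions p (W = diag(1/d_j)), so that
# mu' K mu = sum_j (mu_j - mu_{j-1})^2 / d_j.  Rank m - 1; null space = 1.
.rw1_structure <- function(p) {
  m <- length(p)
  if (m < 2L) return(matrix(0, m, m))
  d <- diff(p)
  D <- diag(m)[-1L, , drop = FALSE] - diag(m)[-m, , drop = FALSE]
  crossprod(D * sqrt(1 / d))
}

# Evaluate the raw cubic polynomial design row(s) for AMP value(s) x (percent).
.poly_basis <- function(x) cbind(1, x, x^2, x^3, deparse.level = 0L)

# Run code with a private RNG stream: the global .Random.seed is restored on
# exit so fitting never perturbs user-level reproducibility.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Split-Rhat (Gelman-Rubin on split chains) for a draws matrix with a chain
# index; returns NA for constant chains.
.split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2L
    if (h < 2L) return(NA_real_)
    pieces <- c(pieces, list(v[seq_len(h)], v[(length(v) - h + 1L):length(v)]))
  }
  n <- length(pieces[[1L]])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 1e-12) 1 else NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.quantile_summary <- function(draws) {
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(.025, .25, .5, .75, .975),
                names = FALSE))
  data.frame(mean = colMeans(draws), q2.5 = qs[, 1L], q25 = qs[, 2L],
             q50 = qs[, 3L], q75 = qs[, 4L], q97.5 = qs[, 5L])
}
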