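# Independent brute-force oracles used to validate the package's fitting
# routines. These deliberately avoid lm()/varimax() and work from the
# closed-form normal equations / the classic pairwise rotation algorithm.

# simple-regression oracle with the full statistics block
ols_oracle <- function(y, x) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  syy <- sum((y - ybar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((y - intercept - slope * x)^2)
  s2 <- rss / (n - 2)
  r2 <- 1 - rss / syy
  Fv <- r2 * (n - 2) / (1 - r2)
  list(
    intercept = intercept, slope = slope,
    se_intercept = sqrt(s2 * (1 / n + xbar^2 / sxx)),
    se_slope = sqrt(s2 / sxx),
    R = sign(slope) * sqrt(r2), R2 = r2,
    R2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    F = Fv, p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE),
    s_resid = sqrt(s2), n = n
  )
}

# raw varimax criterion: summed variance of squared loadings per column
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(apply(L^2, 2, function(v) sum(v^2) / p - (sum(v) / p)^2))
}

# classic Kaiser pairwise-rotation varimax (raw, no row normalization)
varimax_pairwise_oracle <- function(L, max_iter = 2000, tol = 1e-15) {
  p <- nrow(L)
  k <- ncol(L)
  for (iter in seq_len(max_iter)) {
    old <- varimax_criterion(L)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      x <- L[, a]; y <- L[, b]
      u <- x^2 - y^2
      v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * B / p
      den <- C - (A^2 - B^2) / p
      phi <- atan2(num, den) / 4
      cphi <- cos(phi); sphi <- sin(phi)
      L[, a] <- cphi * x + sphi * y
      L[, b] <- -sphi * x + cphi * y
    }
    if (varimax_criterion(L) - old < tol) break
  }
  # same sign convention as the package: largest-magnitude entry positive
  for (j in seq_len(k)) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) L[, j] <- -L[, j]
  }
  L
}

# order-statistics / moment oracle for summary_stats
summary_oracle <- function(v) {
  v <- sort(v[is.finite(v)])
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  m <- sum(v) / n
  list(median = med, mean = m,
       sd = sqrt(sum((v - m)^2) / (n - 1)),
       range = v[n] - v[1])
}
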