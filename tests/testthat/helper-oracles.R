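# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route than the implementation it checks.

# shrink factor by bisection on feasibility (the implementation uses the
# closed-form interval endpoint)
oracle_shrink_bisection <- function(values, mask, target, bounds, tol = 1e-6) {
  x <- values[mask]
  dev <- x - mean(x)
  feasible <- function(s) {
    adj <- target + s * dev
    all(adj >= bounds[1] - 1e-12) && all(adj <= bounds[2] + 1e-12)
  }
  if (feasible(1)) return(1)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

# two-tailed t-test p value by numerical integration of the t density
oracle_t_p <- function(t, df) {
  f <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(f, abs(t), Inf, rel.tol = 1e-12)$value
}

# OLS slope via the raw-sums normal equations (implementation centers first)
oracle_ols_slope <- function(y, x) {
  n <- length(y)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Pearson correlation from explicit sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# small synthetic object image: colored blob on a near-white canvas with
# JPEG-like speckle (+/- 3 around 255) in the background
make_test_object <- function(n = 40, seed = 7) {
  set.seed(seed)
  ras <- array(0, dim = c(n, n, 3))
  speck <- matrix(sample(252:255, n * n, replace = TRUE), n, n)
  for (ch in 1:3) ras[, , ch] <- speck
  cx <- n / 2
  mask <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - cx)^2 + (j - cx)^2 < (n / 3)^2)
  ras[, , 1][mask] <- 170 + round(20 * sin(seq_len(sum(mask))))
  ras[, , 2][mask] <- 120
  ras[, , 3][mask] <- 90
  list(raster = ras, mask = mask)
}
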