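# Independent brute-force oracles used to cross-check the package's
# statistics, plus small fixture builders.

# OLS via explicitly coded normal equations (no lm).
ols_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

quad_design <- function(n_rate) cbind(1, n_rate, n_rate^2)

# Pearson r and two-sided p via the covariance ratio and t transform,
# coded independently of stats::cor.test.
pearson_oracle <- function(x, y) {
  n <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p_value = p)
}

r_squared_oracle <- function(observed, fitted) {
  1 - sum((observed - fitted)^2) / sum((observed - mean(observed))^2)
}

# Random well-conditioned concave calibration: quadratic with a clearly
# resolvable ascending branch and an increasing bridge.
random_concave_set <- function() {
  list(a0 = runif(1, 0.3, 0.8),
       a1 = runif(1, 1e-3, 0.01),
       a2 = -runif(1, 1e-5, 1e-3),
       b0 = runif(1, -0.8, 0.2),
       b1 = runif(1, 0.5, 2))
}

quad_from <- function(s) {
  fit_quadratic_response(c(0, 1, 2, 3), s$a0 + s$a1 * c(0, 1, 2, 3) +
                           s$a2 * c(0, 1, 2, 3)^2)
}

# Noiseless observations at the canonical six N levels from bare
# coefficients, bypassing the trial generator.
noiseless_si <- function(a, n = c(0, 30, 60, 90, 120, 150)) {
  list(n_rate = n, si = a[1] + a[2] * n + a[3] * n^2)
}
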