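# Independent brute-force oracles, deliberately avoiding lm()/cor() so they
# cross-check the implementation rather than repeat it.

# Simple-regression normal equations evaluated directly.
ols_oracle <- function(x, y) {
  n <- length(x)
  d <- n * sum(x^2) - sum(x)^2
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / d
  intercept <- (sum(y) - slope * sum(x)) / n
  fitted <- intercept + slope * x
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2))
}

# Two-predictor normal equations solved explicitly.
plane_oracle <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Pearson r from the covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2) / (n - 1)) *
       sqrt(sum((y - mean(y))^2) / (n - 1)) * (n - 1))
}

# Noise-free Lioumbas sweep on the standard grid.
exact_lioumbas_sweep <- function(a, b, temp = seq(60, 110, 5), ...) {
  viscosity_sweep(temp, exp(a + b * log(temp)^2), ...)
}

# Noise-free Arrhenius sweep.
exact_arrhenius_sweep <- function(mu0, Ea, temp = seq(60, 110, 5), ...) {
  viscosity_sweep(temp, mu0 * exp(Ea / (8.314 * (temp + 273.15))), ...)
}

# Temporary CSV from a data frame.
write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
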