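# Independent oracles: explicit-sum Pearson/OLS and a numerically
# integrated t tail. These never call the package code paths they check.

oracle_pearson_r <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# two-sided tail of the t distribution by numeric integration of the
# explicit density
oracle_t_p <- function(tstat, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(
    dens, abs(tstat), Inf,
    rel.tol = 1e-12, abs.tol = 1e-300
  )$value
  2 * tail
}

oracle_pearson <- function(x, y) {
  r <- oracle_pearson_r(x, y)
  df <- length(x) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = oracle_t_p(tstat, df))
}

# two-sided null tail probability of the sample Pearson r at threshold r0
oracle_pearson_null_tail <- function(r0, n) {
  df <- n - 2
  oracle_t_p(r0 * sqrt(df / (1 - r0^2)), df)
}

oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = slope, intercept = (sum(y) - slope * sum(x)) / n)
}
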