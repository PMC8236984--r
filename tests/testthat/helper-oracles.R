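# Independent oracles the implementation is checked against.

# Exact area under A*(1 - exp(-t/tau)) between t0 and t1, from the
# antiderivative A*(t + tau*exp(-t/tau)).
exp_rise_area_exact <- function(A, tau, t0, t1) {
  antider <- function(t) A * (t + tau * exp(-t / tau))
  antider(t1) - antider(t0)
}

# Ordinary least squares by explicit normal-equations arithmetic.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Pearson r straight from its definitional formula.
pearson_definitional <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Log-spaced grid used by several integration tests.
log_grid <- function(t0, t1, n) exp(seq(log(t0), log(t1), length.out = n))

noise_free_config <- function(...) {
  synthetic_config(noise_sd_rel = 0, noise_sd_abs = 0, ...)
}
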