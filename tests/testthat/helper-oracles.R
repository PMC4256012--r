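# Independent numeric oracles used across the tests.  These deliberately
# avoid the package's own quadrature helpers.

# Trapezoid rule, written out directly.
trapz_o <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

# Mean of an exponential density with rate r truncated to [0, M]
# (closed form; r may be negative).
trunc_exp_mean_o <- function(r, M) {
  if (abs(r) < 1e-12) return(M / 2)
  1 / r - M / expm1(r * M)
}

# CDF of the truncated exponential on [0, M].
trunc_exp_cdf_o <- function(x, r, M) {
  x <- pmin(pmax(x, 0), M)
  if (abs(r) < 1e-12) x / M else expm1(-r * x) / expm1(-r * M)
}

# Reference tasks reused across files.
ref_linear <- function() {
  list(task = task_spec(R_I = 10, P = 5, tau_max = 10),
       u = leisure_utility("linear", 0))
}
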