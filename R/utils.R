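# Internal numerics shared across modules.

# Trapezoidal quadrature on an arbitrary (sorted) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoid, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Differential entropy -int p log p of a gridded density (nats).
# 0 * log(0) is taken as 0.
grid_entropy <- function(x, p) {
  plogp <- ifelse(p > 0, p * log(p), 0)
  -trapz(x, plogp)
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain("`%s` must be a single non-missing number.", name)
  }
  if (!allow_inf && !is.finite(x)) {
    stop_domain("`%s` must be finite.", name)
  }
  if (strict && x <= lower) {
    stop_domain("`%s` must be > %g.", name, lower)
  }
  if (!strict && x < lower) {
    stop_domain("`%s` must be >= %g.", name, lower)
  }
  invisible(x)
}
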