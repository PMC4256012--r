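#' Microscopic utility of leisure
#'
#' Constructs the innate, duration-dependent utility a subject derives from a
#' single leisure bout of length `tau` seconds.  Three canonical forms are
#' supported:
#'
#' * `"linear"`: `U_L(tau) = C_L * tau`, constant marginal utility `C_L`
#'   (utility per second).  Total utility of several short bouts equals that of
#'   one long bout of the same total length, so the subject is indifferent to
#'   how a given amount of leisure is divided.
#' * `"log1p"`: `U_L(tau) = C_L * log(1 + tau)`, strictly concave and defined
#'   at `tau = 0`; marginal utility `C_L / (1 + tau)` is strictly decreasing.
#' * `"log"`: `U_L(tau) = C_L * log(tau)`, strictly concave on `tau > 0`.  This
#'   form is retained because the softmax policy over leisure durations it
#'   induces is exactly a (truncated) gamma distribution
#'   (see [closed_form_distribution()]).
#'
#' Utility units are arbitrary; `C_L` carries them (per second for the linear
#' form, as a dimensionless multiplier of the log otherwise).
#'
#' The family is deliberately a two-field value object with a value/marginal
#' contract ([utility_value()], [utility_marginal()]) so further concave or
#' sigmoidal forms could be added without touching the policy solver.
#'
#' @param form One of `"linear"`, `"log1p"`, `"log"`.
#' @param C_L Non-negative marginal-utility coefficient.
#' @return An object of class `leisure_utility`.
#' @examples
#' u <- leisure_utility("log1p", C_L = 2)
#' utility_value(u, exp(1) - 1)   # = 2
#' utility_marginal(u, 1)         # = 1
#' @export
leisure_utility <- function(form = c("linear", "log1p", "log"), C_L = 1) {
  form <- match.arg(form)
  check_scalar(C_L, "C_L", lower = 0)
  structure(list(form = form, C_L = C_L), class = "leisure_utility")
}

#' @export
print.leisure_utility <- function(x, ...) {
  body <- switch(x$form,
    linear = "C_L * tau",
    log1p  = "C_L * log(1 + tau)",
    log    = "C_L * log(tau)"
  )
  cat(sprintf("<leisure_utility> U_L(tau) = %s, C_L = %g\n", body, x$C_L))
  invisible(x)
}

check_tau_domain <- function(u, tau) {
  if (any(!is.finite(tau))) stop_domain("`tau` must be finite.")
  if (any(tau < 0)) stop_domain("`tau` must be non-negative.")
  if (u$form == "log" && any(tau == 0)) {
    stop_domain("log-form leisure utility is undefined at tau = 0.")
  }
  invisible(tau)
}

#' Evaluate the microscopic utility of leisure
#'
#' @param u A [leisure_utility()].
#' @param tau Vector of leisure durations (seconds, `>= 0`; `> 0` for the
#'   `"log"` form).
#' @return Utility, same length as `tau`.
#' @export
utility_value <- function(u, tau) {
  stopifnot(inherits(u, "leisure_utility"))
  check_tau_domain(u, tau)
  ul_value_unchecked(u, tau)
}

# Internal: vectorised value with log(0) = -Inf allowed (used on the solver
# grid, where exp(beta * -Inf) = 0 gives the correct zero density at tau = 0).
ul_value_unchecked <- function(u, tau) {
  switch(u$form,
    linear = u$C_L * tau,
    log1p  = u$C_L * log1p(tau),
    log    = u$C_L * log(tau)
  )
}

#' Marginal microscopic utility of leisure
#'
#' The derivative of [utility_value()] with respect to duration: constant
#' `C_L` for the linear form, strictly decreasing for the concave forms.
#'
#' @inheritParams utility_value
#' @return Utility per second, same length as `tau`.
#' @export
utility_marginal <- function(u, tau) {
  stopifnot(inherits(u, "leisure_utility"))
  check_tau_domain(u, tau)
  switch(u$form,
    linear = rep_len(u$C_L, length(tau)),
    log1p  = u$C_L / (1 + tau),
    log    = u$C_L / tau
  )
}
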