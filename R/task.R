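#' Cumulative handling time task contingency
#'
#' Bundles the experimenter-controlled parameters of the schedule: the
#' subjective reward intensity delivered after each completed work bout, the
#' price (the cumulative work time, in seconds, required per reward), the
#' range of admissible leisure durations, and the trial duration.
#'
#' Defaults follow the conventions used throughout the package: the leisure
#' duration range upper bound `tau_max` defaults to `20 * P` so that it
#' comfortably dominates the mean of the policy at the lowest payoffs
#' explored, and the trial duration `T` defaults to `25 * P` (trials
#' normalised to a fixed multiple of the price).
#'
#' @param R_I Subjective reward intensity (arbitrary utility units, `> 0`
#'   ordinarily; `0` allowed).
#' @param P Price: seconds of work per reward (`> 0`).
#' @param tau_max Upper bound of the leisure-duration range (seconds, `> 0`).
#' @param T_trial Trial duration in seconds (`>= P`).
#' @return An object of class `task_spec`.
#' @examples
#' task_spec(R_I = 10, P = 5)
#' @export
task_spec <- function(R_I, P, tau_max = 20 * P, T_trial = 25 * P) {
  check_scalar(R_I, "R_I", lower = 0)
  check_scalar(P, "P", lower = 0, strict = TRUE)
  check_scalar(tau_max, "tau_max", lower = 0, strict = TRUE)
  check_scalar(T_trial, "T_trial", lower = 0, strict = TRUE)
  if (T_trial < P) stop_domain("`T_trial` must be at least one price `P`.")
  structure(
    list(R_I = R_I, P = P, tau_max = tau_max, T_trial = T_trial),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "<task_spec> R_I = %g, P = %g s, tau_max = %g s, T = %g s (payoff %g /s)\n",
    x$R_I, x$P, x$tau_max, x$T_trial, x$R_I / x$P
  ))
  invisible(x)
}

#' Policy solver settings
#'
#' @param beta Inverse temperature (per utility unit, `>= 0`).  `beta = 0`
#'   yields the uniform policy over `[0, tau_max]`; `beta = Inf` yields
#'   deterministic, optimal choices and is routed to
#'   [deterministic_policy()].
#' @param grid_n Number of points of the uniform duration grid on
#'   `[0, tau_max]` (`>= 2`).
#' @param include_entropy_in_rate If `TRUE`, the policy entropy divided by
#'   `beta` is added to the per-cycle utility when computing the average
#'   reward rate (the fully entropy-consistent "soft" variant).  The default
#'   `FALSE` uses only microscopic utilities, the rate as conventionally
#'   defined.  At small `beta` the two differ appreciably.
#' @param solver `"iterate"` (damped fixed-point iteration, the default) or
#'   `"root"` (bracketing root-finder on the rate residual).
#' @param eta Damping factor of the fixed-point iteration, in `(0, 1]`.
#' @param tol Convergence tolerance on the reward rate.
#' @param max_iter Iteration cap; non-convergence is flagged, never silent.
#' @return An object of class `policy_settings`.
#' @export
policy_settings <- function(beta = 1, grid_n = 2001,
                            include_entropy_in_rate = FALSE,
                            solver = c("iterate", "root"),
                            eta = 0.5, tol = 1e-10, max_iter = 10000L) {
  check_scalar(beta, "beta", lower = 0, allow_inf = TRUE)
  check_scalar(grid_n, "grid_n", lower = 2)
  check_scalar(eta, "eta", lower = 0, strict = TRUE)
  check_scalar(tol, "tol", lower = 0, strict = TRUE)
  solver <- match.arg(solver)
  structure(
    list(beta = beta, grid_n = as.integer(grid_n),
         include_entropy_in_rate = isTRUE(include_entropy_in_rate),
         solver = solver, eta = eta, tol = tol,
         max_iter = as.integer(max_iter)),
    class = "policy_settings"
  )
}
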