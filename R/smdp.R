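#' Differential Q-value of a leisure bout
#'
#' Expected return of engaging in leisure for `tau` seconds in the
#' post-reward state: the immediate microscopic utility of leisure, minus the
#' average foregone reward (AFR) `rho * tau` — the mean reward sacrificed by
#' committing to the bout while the environment pays `rho` utility per second
#' on average — plus the differential value of the pre-reward state entered
#' afterwards.
#'
#' @param tau Leisure duration(s), seconds, in `[0, tau_max]`.
#' @param rho Average reward rate (utility per second).
#' @param u A [leisure_utility()].
#' @param V_pre Differential value of the pre-reward state (defaults to 0;
#'   Q-values enter the policy only through differences, see
#'   [softmax_policy()]).
#' @param tau_max Upper bound of the admissible duration range.
#' @return `U_L(tau) - rho * tau + V_pre`.
#' @export
q_leisure <- function(tau, rho, u, V_pre = 0, tau_max = Inf) {
  check_scalar(rho, "rho", allow_inf = FALSE)
  if (any(tau > tau_max)) stop_domain("`tau` exceeds `tau_max`.")
  utility_value(u, tau) - rho * tau + V_pre
}

#' Differential Q-value of working
#'
#' Expected return of pre-committing to work for the entire price `P` in the
#' pre-reward state: the reward intensity collected at completion, minus the
#' average foregone reward over the price, plus the value of the post-reward
#' state.
#'
#' @param rho Average reward rate (utility per second).
#' @param task A [task_spec()].
#' @param V_post Differential value of the post-reward state (anchored at 0).
#' @return `R_I - rho * P + V_post`.
#' @export
q_work <- function(rho, task, V_post = 0) {
  check_scalar(rho, "rho")
  stopifnot(inherits(task, "task_spec"))
  task$R_I - rho * task$P + V_post
}

# ---------------------------------------------------------------------------
# Gridded densities

new_policy_density <- function(tau, density, atom = NA_real_) {
  structure(list(tau = tau, density = density, atom = atom),
            class = "policy_density")
}

#' Uniform policy density on `[0, tau_max]`
#' @param tau_max Range upper bound (seconds).
#' @param grid_n Grid size.
#' @return A gridded density (`policy_density`).
#' @export
uniform_policy <- function(tau_max, grid_n = 2001) {
  tau <- seq(0, tau_max, length.out = grid_n)
  new_policy_density(tau, rep(1 / tau_max, grid_n))
}

#' Point (deterministic) policy at a single duration
#'
#' Represented on the grid as a single-node spike whose trapezoidal integral
#' is exactly 1; the `atom` field carries the exact location and is used by
#' moment computations.
#'
#' @param tau0 The chosen duration (seconds).
#' @param tau_max Range upper bound.
#' @param grid_n Grid size.
#' @return A `policy_density` with an atom.
#' @export
point_policy <- function(tau0, tau_max, grid_n = 2001) {
  check_scalar(tau0, "tau0", lower = 0)
  if (tau0 > tau_max) stop_domain("`tau0` exceeds `tau_max`.")
  tau <- seq(0, tau_max, length.out = grid_n)
  h <- tau_max / (grid_n - 1)
  i <- which.min(abs(tau - tau0))
  w <- if (i == 1L || i == grid_n) h / 2 else h
  density <- numeric(grid_n)
  density[i] <- 1 / w
  new_policy_density(tau, density, atom = tau0)
}

policy_moments <- function(pi, u) {
  if (!is.na(pi$atom)) {
    ul <- if (u$form == "log" && pi$atom == 0) -Inf else
      ul_value_unchecked(u, pi$atom)
    return(list(mean_tau = pi$atom, mean_ul = ul, entropy = -Inf))
  }
  ulv <- ul_value_unchecked(u, pi$tau)
  integrand <- ifelse(pi$density > 0, pi$density * ulv, 0)
  list(
    mean_tau = trapz(pi$tau, pi$tau * pi$density),
    mean_ul  = trapz(pi$tau, integrand),
    entropy  = grid_entropy(pi$tau, pi$density)
  )
}

# ---------------------------------------------------------------------------

#' Entropy-regularized softmax policy over leisure durations
#'
#' The maximiser of `E_pi[Q] + H(pi)/beta` over densities on `[0, tau_max]`:
#' `pi(tau) = exp(beta q(tau)) / integral exp(beta q)`.  Computed with
#' max-subtraction for overflow safety and trapezoidal normalization on a
#' uniform grid.  `beta = 0` returns the uniform density `1/tau_max`; adding
#' any constant to `q` leaves the policy unchanged, which is why the
#' differential-value anchor `V_post = 0` is harmless.
#'
#' @param q A function of duration returning utility, or a numeric vector of
#'   Q-values already evaluated on the grid (`-Inf` allowed, giving zero
#'   density).
#' @param beta Inverse temperature (`>= 0`, finite).
#' @param tau_max Range of possible leisure durations (seconds).
#' @param grid_n Grid size.
#' @return A `policy_density` on `[0, tau_max]`.
#' @export
softmax_policy <- function(q, beta, tau_max, grid_n = 2001) {
  check_scalar(beta, "beta", lower = 0)
  tau <- seq(0, tau_max, length.out = grid_n)
  if (beta == 0) {
    return(new_policy_density(tau, rep(1 / tau_max, grid_n)))
  }
  qv <- if (is.function(q)) q(tau) else q
  if (length(qv) != grid_n) stop_domain("`q` has wrong length for the grid.")
  if (any(is.nan(qv)) || any(qv == Inf)) {
    stop_domain("Q-values must be < Inf and not NaN on the grid.")
  }
  w <- exp(beta * (qv - max(qv[is.finite(qv)])))
  z <- trapz(tau, w)
  new_policy_density(tau, w / z)
}

#' Average reward rate of a policy
#'
#' The ratio of the expected total microscopic utility accumulated during one
#' work-leisure cycle (reward intensity plus expected leisure utility) to the
#' expected duration of a cycle (price plus expected leisure duration).  With
#' `include_entropy = TRUE` the policy entropy divided by `beta` is added to
#' the per-cycle utility (the entropy-consistent variant; see
#' [policy_settings()]).
#'
#' @param pi A `policy_density` normalized on `[0, tau_max]`.
#' @param u A [leisure_utility()].
#' @param task A [task_spec()].
#' @param include_entropy Add `H(pi)/beta` to the cycle utility?
#' @param beta Inverse temperature; required if `include_entropy = TRUE`.
#' @return Utility per second.
#' @export
reward_rate <- function(pi, u, task, include_entropy = FALSE, beta = NULL) {
  stopifnot(inherits(pi, "policy_density"), inherits(task, "task_spec"))
  if (is.na(pi$atom) && abs(trapz(pi$tau, pi$density) - 1) > 1e-6) {
    stop_domain("`pi` is not a normalized density.")
  }
  m <- policy_moments(pi, u)
  num <- task$R_I + m$mean_ul
  if (include_entropy) {
    if (is.null(beta) || beta <= 0 || !is.finite(beta)) {
      stop_domain("`include_entropy = TRUE` requires finite `beta` > 0.")
    }
    num <- num + m$entropy / beta
  }
  num / (task$P + m$mean_tau)
}

# Rate as a function of rho for the fixed-point problem.
rate_of_rho <- function(rho, task, u, settings, tau, ulv) {
  qv <- ulv - rho * tau
  pi <- softmax_policy(qv, settings$beta, task$tau_max,
                       grid_n = settings$grid_n)
  reward_rate(pi, u, task,
              include_entropy = settings$include_entropy_in_rate,
              beta = if (settings$include_entropy_in_rate) settings$beta)
}

#' Solve the two-state micro-SMDP
#'
#' Finds the joint fixed point of the softmax policy and the average reward
#' rate: a density `pi* = softmax(beta * (U_L(tau) - rho* tau))` on
#' `[0, tau_max]` together with the rate `rho*` that `pi*` itself produces.
#' The default algorithm is damped fixed-point iteration
#' `rho <- (1 - eta) rho + eta rate(rho)` from `rho0 = R_I/(P + tau_max/2)`,
#' with a bracketing root-finder on `rate(rho) - rho` as fallback (or as the
#' primary solver, `solver = "root"`).  `beta = Inf` is routed to
#' [deterministic_policy()]; `beta = 0` returns the uniform policy directly.
#'
#' @param task A [task_spec()].
#' @param u A [leisure_utility()].
#' @param settings A [policy_settings()].
#' @return A `solved_policy`: the gridded density with its reward rate `rho`,
#'   mean leisure duration, mean leisure utility, entropy, differential state
#'   values (`V_post` anchored at 0, `V_pre = R_I - rho P`), and convergence
#'   information.
#' @examples
#' pol <- solve_policy(task_spec(10, 5, tau_max = 10),
#'                     leisure_utility("linear", 0),
#'                     policy_settings(beta = 1))
#' pol$rho
#' @export
solve_policy <- function(task, u, settings = policy_settings()) {
  stopifnot(inherits(task, "task_spec"), inherits(u, "leisure_utility"),
            inherits(settings, "policy_settings"))
  if (is.infinite(settings$beta)) {
    return(deterministic_policy(task, u, grid_n = settings$grid_n))
  }
  tau <- seq(0, task$tau_max, length.out = settings$grid_n)

  if (settings$beta == 0) {
    pi <- uniform_policy(task$tau_max, settings$grid_n)
    rho <- reward_rate(pi, u, task)
    return(new_solved_policy(pi, rho, u, task, settings,
                             converged = TRUE, iterations = 0L))
  }

  ulv <- ul_value_unchecked(u, tau)
  f <- function(rho) rate_of_rho(rho, task, u, settings, tau, ulv)

  rho <- task$R_I / (task$P + task$tau_max / 2)
  converged <- FALSE
  iterations <- 0L
  if (settings$solver == "iterate") {
    for (i in seq_len(settings$max_iter)) {
      r <- f(rho)
      iterations <- i
      if (abs(r - rho) < settings$tol) {
        rho <- rho + settings$eta * (r - rho)
        converged <- TRUE
        break
      }
      rho <- rho + settings$eta * (r - rho)
    }
  }
  if (!converged) {
    # Bracketing root-finder on g(rho) = rate(rho) - rho.  g(0) > 0 because
    # the cycle utility is positive; the upper end exceeds any attainable rate.
    g <- function(rho) f(rho) - rho
    hi <- (task$R_I + max(0, ulv[length(ulv)], na.rm = TRUE)) / task$P + 1
    while (g(hi) > 0) hi <- hi * 2
    root <- stats::uniroot(g, c(0, hi), tol = 1e-13)
    rho <- root$root
    iterations <- iterations + root$iter
    converged <- abs(g(rho)) < max(settings$tol, 1e-9)
  }

  pi <- softmax_policy(ulv - rho * tau, settings$beta, task$tau_max,
                       grid_n = settings$grid_n)
  new_solved_policy(pi, rho, u, task, settings,
                    converged = converged, iterations = iterations)
}

new_solved_policy <- function(pi, rho, u, task, settings, converged,
                              iterations) {
  m <- policy_moments(pi, u)
  structure(
    list(
      tau = pi$tau, density = pi$density, atom = pi$atom,
      rho = rho,
      mean_leisure = m$mean_tau,
      mean_UL = m$mean_ul,
      entropy = m$entropy,
      V_pre = task$R_I - rho * task$P, V_post = 0,
      converged = converged, iterations = iterations,
      beta = settings$beta, task = task, utility = u, settings = settings
    ),
    class = c("solved_policy", "policy_density")
  )
}

#' @export
print.solved_policy <- function(x, ...) {
  cat(sprintf(
    paste0("<solved_policy> beta = %g, R_I = %g, P = %g s\n",
           "  rho = %.6g /s, mean leisure = %.6g s, TA = %.4f%s%s\n"),
    x$beta, x$task$R_I, x$task$P, x$rho, x$mean_leisure,
    x$task$P / (x$task$P + x$mean_leisure),
    if (!is.na(x$atom)) sprintf(", atom at %.6g s", x$atom) else "",
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

#' Deterministic (beta = Inf) optimal policy
#'
#' The limit of vanishing choice stochasticity: a point policy at the
#' duration maximising the net excess return of leisure
#' `U_L(tau) - rho tau` on `[0, tau_max]` with `rho` self-consistent, which
#' is equivalently the duration maximising the per-cycle reward rate
#' `(R_I + U_L(tau)) / (P + tau)`.  For concave `U_L` an interior optimum
#' satisfies the first-order condition `marginal U_L(tau*) = rho`.  Ties are
#' broken toward the smallest duration.
#'
#' For linear `U_L` the optimum is a corner: all work (`tau* = 0`) when the
#' payoff `R_I / P` exceeds `C_L`, or maximal leisure (`tau* = tau_max`)
#' otherwise — the simplified SMDP always cycles, so the `tau_max` atom
#' stands in for quitting.
#'
#' @inheritParams solve_policy
#' @param grid_n Grid used for the coarse argmax before local refinement.
#' @return A `solved_policy` with an atom.
#' @export
deterministic_policy <- function(task, u, grid_n = 2001) {
  stopifnot(inherits(task, "task_spec"), inherits(u, "leisure_utility"))
  tau <- seq(0, task$tau_max, length.out = grid_n)
  cycle_rate <- function(t) {
    ul <- ul_value_unchecked(u, t)
    (task$R_I + ul) / (task$P + t)
  }
  r <- cycle_rate(tau)
  r[!is.finite(r)] <- -Inf
  i <- which.max(r)  # first maximum: ties toward smallest tau
  tau_star <- tau[i]
  if (i > 1L && i < grid_n) {
    opt <- stats::optimize(cycle_rate, c(tau[i - 1L], tau[i + 1L]),
                           maximum = TRUE, tol = 1e-12)
    if (opt$objective >= r[i]) tau_star <- opt$maximum
  }
  rho <- cycle_rate(tau_star)
  pi <- point_policy(tau_star, task$tau_max, grid_n)
  settings <- policy_settings(beta = Inf, grid_n = grid_n)
  new_solved_policy(pi, rho, u, task, settings,
                    converged = TRUE, iterations = 1L)
}

# ---------------------------------------------------------------------------
# Closed-form leisure-duration distributions

#' Closed-form softmax policy distributions
#'
#' For the linear and logarithmic leisure-utility forms the softmax policy
#' has an exact parametric family:
#'
#' * linear `U_L = C_L tau`: truncated exponential on `[0, tau_max]` with
#'   rate `beta (rho - C_L)`.  A negative rate is legal and means the density
#'   increases toward `tau_max` (the leisure-dominant regime).
#' * log `U_L = C_L log(tau)`: truncated gamma with shape `beta C_L + 1` and
#'   rate `beta rho`.
#'
#' Other forms have no closed form; this is signalled with a condition of
#' class `timealloc_no_closed_form` so callers can fall back to the numeric
#' density.
#'
#' @param u A [leisure_utility()].
#' @param beta Inverse temperature (`> 0`, finite).
#' @param rho Average reward rate.
#' @param tau_max Truncation point (seconds).
#' @return A `leisure_distribution` (family, rate, shape, truncation) with
#'   methods [ldist_density()], [ldist_cdf()], [ldist_mean()],
#'   [ldist_mode()].
#' @export
closed_form_distribution <- function(u, beta, rho, tau_max) {
  stopifnot(inherits(u, "leisure_utility"))
  check_scalar(beta, "beta", lower = 0, strict = TRUE)
  check_scalar(rho, "rho")
  switch(u$form,
    linear = leisure_distribution("truncated_exponential",
                                  rate = beta * (rho - u$C_L),
                                  truncation = tau_max),
    log = leisure_distribution("truncated_gamma",
                               shape = beta * u$C_L + 1,
                               rate = beta * rho, truncation = tau_max),
    stop(structure(
      class = c("timealloc_no_closed_form", "error", "condition"),
      list(message = sprintf(
        "no closed-form policy distribution for '%s' leisure utility",
        u$form), call = sys.call(-1))
    ))
  )
}

#' Parametric leisure-duration distribution
#'
#' @param family One of `"truncated_exponential"`, `"truncated_gamma"`,
#'   `"point"`, `"uniform"`.
#' @param rate Rate parameter (per second; may be negative or zero for the
#'   truncated exponential).
#' @param shape Shape parameter (truncated gamma; `> 0`).
#' @param atom Location of the point mass (family `"point"`).
#' @param truncation Upper truncation `tau_max` (seconds, `> 0`).
#' @return An object of class `leisure_distribution`.
#' @export
leisure_distribution <- function(family = c("truncated_exponential",
                                            "truncated_gamma",
                                            "point", "uniform"),
                                 rate = NA_real_, shape = NA_real_,
                                 atom = NA_real_, truncation) {
  family <- match.arg(family)
  check_scalar(truncation, "truncation", lower = 0, strict = TRUE)
  if (family == "truncated_gamma") {
    check_scalar(shape, "shape", lower = 0, strict = TRUE)
    check_scalar(rate, "rate", lower = 0, strict = TRUE)
  }
  if (family == "truncated_exponential") check_scalar(rate, "rate")
  if (family == "point") {
    check_scalar(atom, "atom", lower = 0)
    if (atom > truncation) stop_domain("`atom` exceeds `truncation`.")
  }
  structure(list(family = family, rate = rate, shape = shape, atom = atom,
                 truncation = truncation),
            class = "leisure_distribution")
}

#' @rdname leisure_distribution
#' @param d A `leisure_distribution`.
#' @param tau Durations at which to evaluate.
#' @export
ldist_density <- function(d, tau) {
  stopifnot(inherits(d, "leisure_distribution"))
  M <- d$truncation
  out <- switch(d$family,
    truncated_exponential = {
      r <- d$rate
      if (r == 0) rep(1 / M, length(tau))
      else exp(-r * tau) / (-expm1(-r * M) / r)
    },
    truncated_gamma =
      stats::dgamma(tau, shape = d$shape, rate = d$rate) /
        stats::pgamma(M, shape = d$shape, rate = d$rate),
    uniform = rep(1 / M, length(tau)),
    point = stop_domain("a point distribution has no density.")
  )
  out[tau < 0 | tau > M] <- 0
  out
}

#' @rdname leisure_distribution
#' @export
ldist_cdf <- function(d, tau) {
  stopifnot(inherits(d, "leisure_distribution"))
  M <- d$truncation
  tauc <- pmin(pmax(tau, 0), M)
  switch(d$family,
    truncated_exponential = {
      r <- d$rate
      if (r == 0) tauc / M else expm1(-r * tauc) / expm1(-r * M)
    },
    truncated_gamma =
      stats::pgamma(tauc, shape = d$shape, rate = d$rate) /
        stats::pgamma(M, shape = d$shape, rate = d$rate),
    uniform = tauc / M,
    point = as.numeric(tau >= d$atom)
  )
}

#' @rdname leisure_distribution
#' @export
ldist_mean <- function(d) {
  stopifnot(inherits(d, "leisure_distribution"))
  M <- d$truncation
  switch(d$family,
    truncated_exponential = {
      r <- d$rate
      if (abs(r) * M < 1e-8) M / 2 - r * M^2 / 12
      else 1 / r - M / expm1(r * M)
    },
    truncated_gamma = (d$shape / d$rate) *
      stats::pgamma(M, shape = d$shape + 1, rate = d$rate) /
      stats::pgamma(M, shape = d$shape, rate = d$rate),
    uniform = M / 2,
    point = d$atom
  )
}

#' @rdname leisure_distribution
#' @export
ldist_mode <- function(d) {
  stopifnot(inherits(d, "leisure_distribution"))
  switch(d$family,
    truncated_exponential = if (d$rate >= 0) 0 else d$truncation,
    truncated_gamma = min(max((d$shape - 1) / d$rate, 0), d$truncation),
    uniform = NA_real_,
    point = d$atom
  )
}
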