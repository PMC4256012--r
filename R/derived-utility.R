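# Macroscopic utility derived from the microscopic SMDP.
#
# For K work-leisure cycles and cumulative leisure L, the per-cycle leisure
# duration must satisfy E_pi[tau] = L/K (the micro-macro consistency
# constraint).  Enforcing it with a Lagrange multiplier lambda and optimising
# the entropy-augmented per-cycle utility over the policy gives the
# exponential-family density pi_lambda ~ exp(beta (U_L(tau) - lambda tau)),
# with lambda tuned so the constraint holds.  The derived macroscopic
# utility evaluated at that constrained optimum is
#
#   U(K, L) = K [ R_I + E[U_L] + H(pi)/beta ] + f(K, L)
#
# where f is the term enforcing the average foregone reward.  This package
# constructs f explicitly as
#
#   f(K, L) = (K P + L) * (1/beta) * int_0^{L/K} H(pi_{lambda(s)})/(P+s)^2 ds,
#
# the unique correction of the homogeneous form K g(L/K) with g(0) = 0 whose
# directional derivative along any budget line cancels the entropy term at
# the optimum.  Along a budget line K P + L = T the derived utility is then
# T * [ (R_I + E[U_L] + H/beta)/(P + l) + G(l) ] with G' = H/(beta (P+l)^2),
# whose stationarity condition reduces to lambda(l) (P + l) = R_I + E[U_L]:
# the optimum coincides with the micro fixed point and the shadow price
# lambda equals the average reward rate rho.  As beta -> Inf the entropy
# terms vanish, f -> 0, and the utility reduces to K (R_I + U_L(L/K)) —
# affine in (K, L) for linear U_L (the perfect-substitutes CES form), and a
# curved-indifference-curve utility for concave U_L.

#' Constrained softmax policy for a target per-cycle leisure
#'
#' The softmax density with the Lagrange multiplier `lambda` in the role of
#' the reward rate, `pi(tau) ~ exp(beta (U_L(tau) - lambda tau))`, with
#' `lambda` found by bracketing root search (expanding brackets) so the
#' policy's mean leisure duration equals `L_per_cycle`.
#'
#' @param u A [leisure_utility()].
#' @param beta Inverse temperature (`> 0`, finite).
#' @param L_per_cycle Target mean leisure per cycle, in `(0, tau_max)`.
#' @param tau_max Duration range upper bound.
#' @param grid_n Grid size.
#' @return A list: `policy` (a `policy_density`), `lambda`, `residual`
#'   (achieved mean minus target).
#' @export
constrained_policy <- function(u, beta, L_per_cycle, tau_max,
                               grid_n = 2001) {
  stopifnot(inherits(u, "leisure_utility"))
  check_scalar(beta, "beta", lower = 0, strict = TRUE)
  check_scalar(L_per_cycle, "L_per_cycle", lower = 0)
  if (L_per_cycle <= 0 || L_per_cycle >= tau_max) {
    stop_domain(
      "`L_per_cycle` = %g is not achievable: it must lie strictly between 0 and tau_max = %g.",
      L_per_cycle, tau_max)
  }
  tau <- seq(0, tau_max, length.out = grid_n)
  ulv <- ul_value_unchecked(u, tau)
  mean_at <- function(lambda) {
    pi <- softmax_policy(ulv - lambda * tau, beta, tau_max, grid_n)
    trapz(tau, tau * pi$density)
  }
  g <- function(lambda) mean_at(lambda) - L_per_cycle
  # E[tau] is strictly decreasing in lambda; expand the bracket until it
  # straddles the target.
  lo <- -1; hi <- 1
  while (g(hi) > 0) { lo <- hi; hi <- hi * 2
    if (hi > 1e12) stop_domain("`L_per_cycle` not achievable (too small).") }
  while (g(lo) < 0) { hi <- lo; lo <- lo * 2
    if (lo < -1e12) stop_domain("`L_per_cycle` not achievable (too large).") }
  lambda <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  pi <- softmax_policy(ulv - lambda * tau, beta, tau_max, grid_n)
  list(policy = pi, lambda = lambda, residual = g(lambda))
}

#' Derive the macroscopic utility induced by the micro-SMDP
#'
#' Builds the macroscopic utility function over accumulated rewards `K` and
#' cumulative leisure `L` that is consistent with the microscopic softmax
#' choices on average: per-cycle reward utility, expected leisure utility
#' and policy entropy under the constrained-optimal policy (see
#' [constrained_policy()]), plus the average-foregone-reward-enforcing
#' correction `f` constructed so that the budget-constrained optimum of the
#' derived utility reproduces the SMDP allocation (construction documented
#' in the methods vignette).  At `beta = Inf` the utility reduces to
#' `K * (R_I + U_L(L/K))`: affine (the perfect-substitutes labor-supply
#' form) for linear leisure utility, curved for concave.
#'
#' @param u A [leisure_utility()].
#' @param beta Inverse temperature, `> 0` or `Inf`.  `beta = 0` is rejected:
#'   the entropy term of the derived utility diverges.
#' @param task A [task_spec()].
#' @param grid_n Grid size used for the constrained policies (match the
#'   micro solver's for micro-macro comparisons).
#' @return An object of class `derived_macro_utility` with fields
#'   `evaluator` (a function of `(K, L)`), `lambda_at` (function of the
#'   per-cycle leisure), `afr_correction` (the function `f(K, L)`), and the
#'   source `(u, beta, task)`.
#' @export
derive_macro_utility <- function(u, beta, task, grid_n = 2001) {
  stopifnot(inherits(u, "leisure_utility"), inherits(task, "task_spec"))
  check_scalar(beta, "beta", lower = 0, allow_inf = TRUE)
  if (beta == 0) {
    stop_domain(paste0(
      "the derived macroscopic utility diverges at beta = 0 ",
      "(the entropy term H/beta is unbounded)."))
  }
  P <- task$P
  R_I <- task$R_I
  tau_max <- task$tau_max

  if (is.infinite(beta)) {
    evaluator <- function(K, L) {
      mapply(function(K, L) {
        if (K < 0 || L < 0) stop_domain("`K` and `L` must be >= 0.")
        if (K == 0) return(0)
        K * (R_I + ul_value_unchecked(u, L / K))
      }, K, L)
    }
    obj <- list(
      evaluator = evaluator,
      lambda_at = function(l) utility_marginal(u, l),
      afr_correction = function(K, L) 0 * K,
      cycle_terms = function(l) list(
        mean_ul = ul_value_unchecked(u, l), entropy = -Inf,
        lambda = utility_marginal(u, l)),
      u = u, beta = beta, task = task, grid_n = grid_n
    )
    class(obj) <- "derived_macro_utility"
    return(obj)
  }

  # finite beta ------------------------------------------------------------
  tau <- seq(0, tau_max, length.out = grid_n)
  ulv <- ul_value_unchecked(u, tau)

  cycle_terms <- function(l) {
    cp <- constrained_policy(u, beta, l, tau_max, grid_n)
    dens <- cp$policy$density
    integrand <- ifelse(dens > 0, dens * ulv, 0)
    list(
      mean_ul = trapz(tau, integrand),
      entropy = grid_entropy(tau, dens),
      lambda = cp$lambda
    )
  }

  # G(l) = (1/beta) int_0^l H(s)/(P+s)^2 ds; the integrand has an integrable
  # logarithmic singularity at 0 (H -> -Inf as the policy concentrates), so
  # the quadrature grid is quadratically refined toward 0.  The cumulative
  # integral is computed once per derived object and splined; G enters the
  # evaluator only through its value (the optimum location uses the exact
  # directional derivative, see macro_optimum()), so spline error only
  # perturbs reported utility levels, not allocations.
  cache <- new.env(parent = emptyenv())
  G <- function(l) {
    if (l <= 0) return(0)
    if (is.null(cache$G_fun)) {
      ls <- tau_max * (1e-6 + (1 - 2e-6) * seq(0, 1, length.out = 513)^2)
      hs <- vapply(ls, function(s) cycle_terms(s)$entropy, numeric(1))
      cum <- cumtrapz(ls, hs / (P + ls)^2) / beta
      cache$G_fun <- stats::splinefun(ls, cum, method = "natural")
      cache$l_max <- ls[length(ls)]
    }
    cache$G_fun(min(l, cache$l_max))
  }

  afr_correction <- function(K, L) {
    mapply(function(K, L) (K * P + L) * G(L / K), K, L)
  }

  evaluator <- function(K, L) {
    mapply(function(K, L) {
      if (K < 0 || L < 0) stop_domain("`K` and `L` must be >= 0.")
      if (K == 0) return(0)
      l <- L / K
      ct <- cycle_terms(l)
      val <- K * (R_I + ct$mean_ul + ct$entropy / beta) +
        (K * P + L) * G(l)
      if (!is.finite(val)) {
        stop_domain("derived utility is not finite at (K = %g, L = %g).",
                    K, L)
      }
      val
    }, K, L)
  }

  obj <- list(
    evaluator = evaluator,
    lambda_at = function(l) cycle_terms(l)$lambda,
    afr_correction = afr_correction,
    cycle_terms = cycle_terms,
    u = u, beta = beta, task = task, grid_n = grid_n
  )
  class(obj) <- "derived_macro_utility"
  obj
}

#' @export
print.derived_macro_utility <- function(x, ...) {
  cat(sprintf(
    "<derived_macro_utility> %s leisure utility (C_L = %g), beta = %g, R_I = %g, P = %g s\n",
    x$u$form, x$u$C_L, x$beta, x$task$R_I, x$task$P))
  invisible(x)
}

#' Budget-constrained optimum of a derived macroscopic utility
#'
#' Maximizes the derived evaluator over the budget line `K P + L = T`,
#' parameterized by the per-cycle leisure `l = L/K` in `[0, tau_max]` (the
#' admissible duration range; `K = T/(P + l)` is never zero because every
#' cycle contains a price-long work bout).  The search combines a coarse
#' scan of the directional derivative of the evaluator along the budget
#' line — by the envelope theorem equal to
#' `T (lambda(l)(P + l) - (R_I + E[U_L])) / (P + l)^2` — with bracketing
#' root refinement; corners are handled by the derivative's sign.
#'
#' @param w A [derive_macro_utility()] result.
#' @param bc A [budget_constraint()]; its price must match the task's.
#' @param report_utility Also evaluate the derived utility at the optimum
#'   (requires the AFR-correction integral; the allocation itself does
#'   not).
#' @return A one-row tibble: `K`, `W_total`, `L_total`, `TA`, `lambda`,
#'   `utility` (`NA` unless `report_utility`).
#' @export
macro_optimum <- function(w, bc, report_utility = TRUE) {
  stopifnot(inherits(w, "derived_macro_utility"),
            inherits(bc, "budget_constraint"))
  if (abs(bc$P - w$task$P) > 1e-12) {
    stop_domain("budget price differs from the task price.")
  }
  P <- w$task$P
  R_I <- w$task$R_I
  tau_max <- w$task$tau_max
  T_trial <- bc$T_trial

  if (is.infinite(w$beta)) {
    # deterministic limit: maximize (R_I + U_L(l)) / (P + l) directly
    pol <- deterministic_policy(w$task, w$u, grid_n = w$grid_n)
    l_hat <- pol$atom
    lambda <- pol$rho
  } else {
    dV <- function(l) {
      ct <- w$cycle_terms(l)
      ct$lambda * (P + l) - (R_I + ct$mean_ul)
    }
    # scan for the sign change of the directional derivative (+ -> -)
    ls <- tau_max * c(1e-6, 1e-5, 1e-4, 1e-3,
                      seq(0.01, 0.999, length.out = 60))
    dv <- vapply(ls, dV, numeric(1))
    if (all(dv > 0)) {
      l_hat <- tau_max
      lambda <- w$lambda_at(tau_max * 0.999999)
    } else if (all(dv < 0)) {
      l_hat <- 0
      lambda <- NA_real_
    } else {
      i <- which(dv[-length(dv)] > 0 & dv[-1] <= 0)[1]
      root <- stats::uniroot(dV, c(ls[i], ls[i + 1]), tol = 1e-13)
      l_hat <- root$root
      lambda <- w$cycle_terms(l_hat)$lambda
    }
  }

  K <- T_trial / (P + l_hat)
  L <- K * l_hat
  util <- if (report_utility) {
    tryCatch(w$evaluator(max(K, 1e-12), L), error = function(e) NA_real_)
  } else NA_real_
  macro_allocation(K, L, T_trial, P, lambda = lambda, utility = util)
}

#' Micro-macro consistency report
#'
#' Solves the micro-SMDP, derives the macroscopic utility, finds its
#' budget-constrained optimum, and compares: the macroscopic optimum should
#' reproduce the SMDP's average allocation (`K = T/(P + E[tau])`,
#' `L = K E[tau]`), and the shadow price `lambda` should equal the average
#' reward rate `rho`.  Discrepancies are reported, not raised.
#'
#' @param u A [leisure_utility()].
#' @param beta Inverse temperature (`> 0` or `Inf`).
#' @param task A [task_spec()].
#' @param bc A [budget_constraint()]; defaults to the task's trial duration.
#' @param grid_n Grid size shared by the micro and macro computations.
#' @return A one-row tibble: `TA_macro`, `TA_micro`, `delta_TA`, `lambda`,
#'   `rho`, `delta_lambda_rho`.
#' @export
consistency_check <- function(u, beta, task,
                              bc = budget_constraint(task$T_trial, task$P),
                              grid_n = 2001) {
  pol <- solve_policy(task, u, policy_settings(beta = beta, grid_n = grid_n))
  ta_micro <- time_allocation(pol)
  w <- derive_macro_utility(u, beta, task, grid_n = grid_n)
  opt <- macro_optimum(w, bc, report_utility = FALSE)
  tibble::tibble(
    TA_macro = opt$TA, TA_micro = ta_micro,
    delta_TA = abs(opt$TA - ta_micro),
    lambda = opt$lambda, rho = pol$rho,
    delta_lambda_rho = abs(opt$lambda - pol$rho)
  )
}
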