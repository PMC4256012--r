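#' CES macroscopic utility parameters
#'
#' The commonly assumed constant-elasticity-of-substitution macroscopic
#' utility over accumulated rewards `K` and cumulative leisure time `L`:
#' `U(K, L) = (w_K K)^sigma + (w_L L)^sigma`.  `sigma = 1` is the
#' perfect-substitutes case (linear indifference curves, all-or-none
#' allocation); `0 < sigma < 1` gives imperfect substitutability, curved
#' indifference curves, and partial allocation.
#'
#' @param sigma Substitutability exponent, in `(0, 1]`.
#' @param w_K Weight on rewards (utility per reward; typically the reward
#'   intensity `R_I`).
#' @param w_L Weight on leisure (utility per second; typically `C_L`).
#' @return An object of class `ces_params`.
#' @export
ces_params <- function(sigma, w_K, w_L) {
  check_scalar(sigma, "sigma")
  if (sigma <= 0 || sigma > 1) stop_domain("`sigma` must be in (0, 1].")
  check_scalar(w_K, "w_K", lower = 0)
  check_scalar(w_L, "w_L", lower = 0)
  structure(list(sigma = sigma, w_K = w_K, w_L = w_L), class = "ces_params")
}

#' @rdname ces_params
#' @param K Rewards accumulated (`>= 0`, fractional allowed).
#' @param L Cumulative leisure time (seconds, `>= 0`).
#' @param p A [ces_params()].
#' @return Utility (vectorised over `K`, `L`).
#' @export
ces_utility <- function(K, L, p) {
  stopifnot(inherits(p, "ces_params"))
  if (any(K < 0) || any(L < 0)) stop_domain("`K` and `L` must be >= 0.")
  (p$w_K * K)^p$sigma + (p$w_L * L)^p$sigma
}

#' Budget constraint of a fixed-duration trial
#'
#' The feasible combinations of rewards and leisure in a trial of length
#' `T`: `K * P + L = T` with `K, L >= 0`.
#'
#' @param T_trial Trial duration (seconds, `>= 0`).
#' @param P Price (seconds per reward, `> 0`).
#' @return An object of class `budget_constraint`.
#' @export
budget_constraint <- function(T_trial, P) {
  check_scalar(T_trial, "T_trial", lower = 0)
  check_scalar(P, "P", lower = 0, strict = TRUE)
  structure(list(T_trial = T_trial, P = P), class = "budget_constraint")
}

#' Budget-constrained CES optimum
#'
#' Maximizes [ces_utility()] on the budget line.  With `sigma = 1` the
#' optimum is a corner set by comparing the return per second of work
#' (`w_K / P`) with that of leisure (`w_L`): all work if work pays more, all
#' leisure otherwise.  With `sigma < 1` the optimum is the interior tangency
#' `(w_K^sigma K^(sigma-1)) / P = w_L^sigma L^(sigma-1)`, solved in closed
#' form.
#'
#' @param p A [ces_params()].
#' @param bc A [budget_constraint()].
#' @return A tibble (one row): `K`, `W_total`, `L_total`, `TA`, `utility`.
#' @export
optimal_allocation <- function(p, bc) {
  stopifnot(inherits(p, "ces_params"), inherits(bc, "budget_constraint"))
  T_trial <- bc$T_trial
  P <- bc$P
  if (T_trial == 0) {
    return(macro_allocation(0, 0, T_trial, P, utility = 0))
  }
  if (p$sigma == 1) {
    work_wins <- p$w_K / P > p$w_L
    L <- if (work_wins) 0 else T_trial
  } else {
    # tangency: sigma w_K^s K^(s-1) / P = sigma w_L^s L^(s-1), K = (T - L)/P
    # => L = c * K with c = (w_L^s P / w_K^s)^(1/(s-1))
    s <- p$sigma
    if (p$w_L == 0) {
      L <- 0
    } else if (p$w_K == 0) {
      L <- T_trial
    } else {
      cc <- (p$w_L^s * P / p$w_K^s)^(1 / (1 - s))
      L <- T_trial * cc / (P + cc)
    }
  }
  K <- (T_trial - L) / P
  macro_allocation(K, L, T_trial, P, utility = ces_utility(K, L, p))
}

macro_allocation <- function(K, L, T_trial, P, ...) {
  tibble::tibble(K = K, W_total = K * P, L_total = L,
                 TA = if (T_trial > 0) K * P / T_trial else 0, ...)
}

#' Indifference curves of a macroscopic utility
#'
#' Iso-utility polylines in the `(L, K)` plane, extracted by
#' marching squares on an evaluation grid.  For the perfect-substitutes CES
#' these are straight lines of slope `-w_L / w_K`; for `sigma < 1` the slope
#' magnitude decreases along increasing `L` (diminishing marginal rate of
#' substitution).
#'
#' @param utility Either a function `(K, L) -> utility` (vectorised), a
#'   [ces_params()], or a [derive_macro_utility()] result.
#' @param levels Utility levels to trace.
#' @param K_max,L_max Upper corners of the evaluation window.
#' @param n Grid resolution per axis.
#' @return A tibble with columns `level`, `piece`, `L`, `K`.
#' @export
indifference_curves <- function(utility, levels, K_max, L_max, n = 201) {
  f <- as_macro_utility_fn(utility)
  Ks <- seq(0, K_max, length.out = n)
  Ls <- seq(0, L_max, length.out = n)
  z <- outer(Ls, Ks, function(l, k) f(k, l))
  cl <- grDevices::contourLines(x = Ls, y = Ks, z = z, levels = levels)
  if (length(cl) == 0) {
    return(tibble::tibble(level = numeric(), piece = integer(),
                          L = numeric(), K = numeric()))
  }
  purrr::imap_dfr(cl, function(seg, i) {
    tibble::tibble(level = seg$level, piece = as.integer(i),
                   L = seg$x, K = seg$y)
  })
}

as_macro_utility_fn <- function(utility) {
  if (is.function(utility)) return(utility)
  if (inherits(utility, "ces_params")) {
    return(function(K, L) ces_utility(K, L, utility))
  }
  if (inherits(utility, "derived_macro_utility")) return(utility$evaluator)
  stop_domain("cannot interpret `utility` as a macroscopic utility.")
}

# ---------------------------------------------------------------------------
# Generalized matching: the mountain model

#' Generalized-matching (mountain) parameters
#'
#' @param a Matching exponent (`> 0`): `a > 1` over-matching, `a < 1`
#'   under-matching.
#' @param P_e Anchor price (seconds): the price at which, for a maximal
#'   subjective reward intensity `R_max`, the subject allocates half its
#'   time to work.
#' @param R_max Maximum subjective reward intensity (utility units).
#' @return An object of class `mountain_params`.
#' @export
mountain_params <- function(a, P_e, R_max) {
  check_scalar(a, "a", lower = 0, strict = TRUE)
  check_scalar(P_e, "P_e", lower = 0, strict = TRUE)
  check_scalar(R_max, "R_max", lower = 0, strict = TRUE)
  structure(list(a = a, P_e = P_e, R_max = R_max), class = "mountain_params")
}

#' Time allocation under the generalized matching law
#'
#' Matches the time-allocation odds to the payoff ratio raised to the
#' matching exponent: `TA / (1 - TA) = (q_w / q_l)^a`, with work payoff
#' `q_w = R_I / P` and the leisure payoff anchored at `q_l = R_max / P_e` so
#' that `TA(R_max, P_e) = 1/2` by construction.
#'
#' @param R_I Reward intensity (vectorised).
#' @param P Price in seconds (vectorised).
#' @param m A [mountain_params()].
#' @return TA in `(0, 1)`.
#' @export
matching_ta <- function(R_I, P, m) {
  stopifnot(inherits(m, "mountain_params"))
  if (any(R_I <= 0) || any(P <= 0)) stop_domain("arguments must be > 0.")
  q_w <- R_I / P
  q_l <- m$R_max / m$P_e
  ratio_a <- (q_w / q_l)^m$a
  ratio_a / (ratio_a + 1)
}

#' Mountain-model TA surface
#'
#' Evaluates [matching_ta()] on a reward-intensity by price grid.  The
#' resulting contours increase smoothly with reward intensity and decrease
#' smoothly with price — strictly monotone along both axes, which is exactly
#' what the micro-derived surface of [ta_sweep()] need not be for concave
#' leisure utility.
#'
#' @param R_I_grid,P_grid Positive ascending grids.
#' @param m A [mountain_params()].
#' @return A tibble (class `ta_sweep`) with `R_I`, `P`, `TA`.
#' @export
mountain_surface <- function(R_I_grid, P_grid, m) {
  stopifnot(all(R_I_grid > 0), all(P_grid > 0),
            !is.unsorted(R_I_grid), !is.unsorted(P_grid))
  out <- tidyr::expand_grid(R_I = as.numeric(R_I_grid),
                            P = as.numeric(P_grid))
  out <- dplyr::mutate(out, TA = matching_ta(.data$R_I, .data$P, m))
  class(out) <- c("ta_sweep", class(out))
  out
}
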