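#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved policy into its leisure-duration density
#'
#' @param x A `solved_policy`.
#' @param ... Unused.
#' @return A tibble with `tau_s`, `density_per_s`, `cdf`, and `q` (the
#'   differential Q-value of leisure at the solved reward rate).
#' @export
tidy.solved_policy <- function(x, ...) {
  tibble::tibble(
    tau_s = x$tau,
    density_per_s = x$density,
    cdf = {
      cs <- cumtrapz(x$tau, x$density)
      cs / cs[length(cs)]
    },
    q = ul_value_unchecked(x$utility, x$tau) - x$rho * x$tau + x$V_pre
  )
}

#' One-row summary of a solved policy
#'
#' @param x A `solved_policy`.
#' @param ... Unused.
#' @return A tibble: `beta`, `R_I`, `P_s`, `rho`, `mean_leisure_s`,
#'   `mode_leisure_s`, `entropy_nats`, `TA`, `V_pre`, `converged`,
#'   `iterations`.
#' @export
glance.solved_policy <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, R_I = x$task$R_I, P_s = x$task$P,
    rho = x$rho, mean_leisure_s = x$mean_leisure,
    mode_leisure_s = policy_mode(x), entropy_nats = x$entropy,
    TA = time_allocation(x), V_pre = x$V_pre,
    converged = x$converged, iterations = x$iterations
  )
}

#' Plot a solved leisure-duration policy
#'
#' @param object A `solved_policy`.
#' @param ... Unused.
#' @return A ggplot of the density (a vertical line for point policies).
#' @export
autoplot.solved_policy <- function(object, ...) {
  df <- tidy.solved_policy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_s,
                                        y = .data$density_per_s))
  p <- if (!is.na(object$atom)) {
    p + ggplot2::geom_vline(xintercept = object$atom, linewidth = 1)
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(
    x = "leisure duration (s)", y = "policy density (1/s)",
    title = sprintf("beta = %g, R_I = %g, P = %g s, rho = %.3g /s",
                    object$beta, object$task$R_I, object$task$P,
                    object$rho)
  )
}

#' Plot a time-allocation surface
#'
#' Raster of TA over the reward-intensity by price plane with iso-TA
#' contours overlaid, for either a micro-model [ta_sweep()] or a
#' [mountain_surface()].
#'
#' @param object A `ta_sweep` tibble.
#' @param levels Contour levels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ta_sweep <- function(object, levels = seq(0.1, 0.9, by = 0.1),
                              ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$R_I, y = .data$P)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$TA)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$TA), breaks = levels,
                          colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "reward intensity", y = "price (s)", fill = "TA")
}

#' Plot an ethogram
#'
#' Bar-style rendering of work and leisure bouts over trial time, one row
#' per trial, with reward events marked.
#'
#' @param object An ethogram tibble from [simulate_trial()] or
#'   [simulate_trials()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ethogram <- function(object, ...) {
  rewards <- attr(object, "rewards")
  if (is.null(rewards)) {
    rewards <- tibble::tibble(trial_id = object$trial_id[1],
                              time_s = attr(object, "reward_times"))
  }
  p <- ggplot2::ggplot(object) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$onset_s, xmax = .data$onset_s + .data$duration_s,
      ymin = .data$trial_id - 0.4, ymax = .data$trial_id + 0.4,
      fill = .data$kind)) +
    ggplot2::scale_fill_manual(values = c(work = "grey30",
                                          leisure = "white")) +
    ggplot2::labs(x = "time (s)", y = "trial", fill = NULL)
  if (nrow(rewards) > 0) {
    p <- p + ggplot2::geom_point(
      data = rewards,
      ggplot2::aes(x = .data$time_s, y = .data$trial_id + 0.45),
      shape = 25, size = 1.5, fill = "black")
  }
  p
}

#' @export
autoplot.ethogram_set <- autoplot.ethogram

#' Tidy a derived macroscopic utility into indifference curves
#'
#' Uses the homogeneity of the derived utility (`U(K, L) = K Psi(L/K)`):
#' each indifference curve is traced in closed form as
#' `K = level / Psi(l)`, `L = l K` over the admissible per-cycle leisure
#' range, rather than by marching squares.
#'
#' @param x A `derived_macro_utility`.
#' @param levels Utility levels to trace.
#' @param n Points per curve.
#' @param ... Unused.
#' @return A tibble with `level`, `L`, `K`.
#' @export
tidy.derived_macro_utility <- function(x, levels, n = 101, ...) {
  tau_max <- x$task$tau_max
  ls <- tau_max * (1e-4 + (1 - 2e-4) * seq(0, 1, length.out = n)^2)
  psi <- vapply(ls, function(l) {
    x$evaluator(1, l)
  }, numeric(1))
  keep <- is.finite(psi) & psi > 0
  purrr::map_dfr(levels, function(lev) {
    K <- lev / psi[keep]
    tibble::tibble(level = lev, L = ls[keep] * K, K = K)
  })
}

#' @rdname tidy.derived_macro_utility
#' @param object A `derived_macro_utility`.
#' @export
autoplot.derived_macro_utility <- function(object, levels = NULL, n = 101,
                                           ...) {
  if (is.null(levels)) {
    ref <- object$evaluator(1, min(1, object$task$tau_max / 2))
    levels <- ref * seq(2, 20, length.out = 6)
  }
  df <- tidy.derived_macro_utility(object, levels = levels, n = n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$K,
                                   group = .data$level,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cumulative leisure L (s)", y = "rewards K",
                  colour = "utility")
}

#' One-row summary of a derived macroscopic utility
#'
#' @param x A `derived_macro_utility`.
#' @param ... Unused.
#' @return A tibble: `form`, `C_L`, `beta`, `R_I`, `P_s`, `tau_max_s`.
#' @export
glance.derived_macro_utility <- function(x, ...) {
  tibble::tibble(form = x$u$form, C_L = x$u$C_L, beta = x$beta,
                 R_I = x$task$R_I, P_s = x$task$P,
                 tau_max_s = x$task$tau_max)
}
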