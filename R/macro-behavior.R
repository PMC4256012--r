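#' Time allocation of a solved policy
#'
#' The proportion of trial time spent working.  Computed per cycle: each
#' cycle is `P` seconds of work plus on average `E[tau]` seconds of leisure,
#' so `TA = P / (P + E[tau])`, which equals cumulative work over trial time
#' for whole cycles.  Finite-trial, sampled TA lives in [simulate_trial()].
#'
#' @param policy A `solved_policy` (or anything with a `mean_leisure` field).
#' @param task A [task_spec()]; defaults to the task the policy was solved
#'   for.
#' @return TA in `[0, 1]`.
#' @export
time_allocation <- function(policy, task = policy$task) {
  stopifnot(inherits(task, "task_spec"))
  task$P / (task$P + policy$mean_leisure)
}

#' Sweep the micro-SMDP over a reward-intensity by price grid
#'
#' Solves the SMDP at every `(R_I, P)` cell and records the macroscopic
#' observables: time allocation, reward rate, mean of the leisure-duration
#' distribution, and its mode (from [closed_form_distribution()] where a
#' closed form exists, otherwise the grid argmax of the density).  The
#' resulting TA surface over the plane is the micro-model counterpart of the
#' generalized-matching "mountain" ([mountain_surface()]).
#'
#' `tau_max` and the trial duration scale with the price of each cell (the
#' [task_spec()] defaults) unless overridden.
#'
#' @param R_I_grid,P_grid Positive, ascending grids.
#' @param u A [leisure_utility()].
#' @param settings A [policy_settings()].
#' @param tau_max Optional fixed duration range; default `20 * P` per cell.
#' @return A tibble (class `ta_sweep`) with columns `R_I`, `P`, `rho`,
#'   `mean_leisure`, `mode_leisure`, `TA`, `converged`.
#' @export
ta_sweep <- function(R_I_grid, P_grid, u, settings = policy_settings(),
                     tau_max = NULL) {
  stopifnot(all(R_I_grid > 0), all(P_grid > 0),
            !is.unsorted(R_I_grid), !is.unsorted(P_grid))
  cells <- tidyr::expand_grid(R_I = as.numeric(R_I_grid),
                              P = as.numeric(P_grid))
  rows <- purrr::pmap(cells, function(R_I, P) {
    tm <- if (is.null(tau_max)) 20 * P else tau_max
    task <- task_spec(R_I = R_I, P = P, tau_max = tm)
    pol <- solve_policy(task, u, settings)
    tibble::tibble(
      R_I = R_I, P = P, rho = pol$rho,
      mean_leisure = pol$mean_leisure,
      mode_leisure = policy_mode(pol),
      TA = time_allocation(pol),
      converged = pol$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ta_sweep", class(out))
  out
}

# Mode of the leisure-duration distribution of a solved policy: exact where a
# closed form exists, otherwise argmax of the gridded density.
policy_mode <- function(pol) {
  if (!is.na(pol$atom)) return(pol$atom)
  if (is.finite(pol$beta) && pol$beta > 0 &&
      pol$utility$form %in% c("linear", "log")) {
    d <- closed_form_distribution(pol$utility, pol$beta, pol$rho,
                                  pol$task$tau_max)
    return(ldist_mode(d))
  }
  pol$tau[which.max(pol$density)]
}

#' Iso-TA contours of a sweep
#'
#' Marching-squares contour extraction (linear interpolation, no smoothing —
#' smoothing could manufacture or hide the non-monotonic contours that
#' distinguish concave leisure utility) on the `(R_I, P)` plane.
#'
#' @param result A [ta_sweep()] (or any tibble with `R_I`, `P` and a value
#'   column).
#' @param levels TA levels in `(0, 1)`.
#' @param value Name of the value column (default `"TA"`).
#' @return A tibble with columns `level`, `piece`, `R_I`, `P`; zero rows for
#'   empty contours.
#' @export
ta_contours <- function(result, levels = c(0.25, 0.5, 0.75), value = "TA") {
  stopifnot(all(levels > 0 & levels < 1) || value != "TA")
  xs <- sort(unique(result$R_I))
  ys <- sort(unique(result$P))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(result$R_I, xs), match(result$P, ys))] <- result[[value]]
  if (anyNA(z)) stop_domain("sweep is not a complete R_I x P grid.")
  # a constant field legitimately has no interior contours
  cl <- suppressWarnings(
    grDevices::contourLines(x = xs, y = ys, z = z, levels = levels))
  if (length(cl) == 0) {
    return(tibble::tibble(level = numeric(), piece = integer(),
                          R_I = numeric(), P = numeric()))
  }
  purrr::imap_dfr(cl, function(seg, i) {
    tibble::tibble(level = seg$level, piece = as.integer(i),
                   R_I = seg$x, P = seg$y)
  })
}

#' Locate a time-allocation reversal along price
#'
#' Scans a sweep at fixed reward intensity for a pair of prices
#' `P1 < P2` with `TA(P2) > TA(P1) + tol`: the signature, for concave
#' leisure utility, that time allocation can increase rather than decrease
#' with price.  For linear utility no such pair should exceed grid noise.
#'
#' @param result A [ta_sweep()].
#' @param R_I The reward intensity at which to scan (must be in the sweep).
#' @param tol Minimum TA increase that counts as a reversal.
#' @return A one-row tibble (`P1`, `P2`, `TA1`, `TA2`, `delta`) for the
#'   largest reversal found, or a zero-row tibble if none.
#' @export
find_ta_reversal <- function(result, R_I = max(result$R_I), tol = 1e-6) {
  sl <- dplyr::arrange(dplyr::filter(result, .data$R_I == !!R_I), .data$P)
  if (nrow(sl) < 2) stop_domain("R_I = %g not found in the sweep.", R_I)
  # best (P1, P2) pair: max over P2 of TA(P2) - min TA over P1 <= P2
  cm <- cummin(sl$TA)
  i1 <- match(cm, sl$TA)          # index of running minimum
  delta <- sl$TA - cm
  j <- which.max(delta)
  if (delta[j] <= tol) {
    return(tibble::tibble(P1 = numeric(), P2 = numeric(), TA1 = numeric(),
                          TA2 = numeric(), delta = numeric()))
  }
  tibble::tibble(P1 = sl$P[i1[j]], P2 = sl$P[j],
                 TA1 = sl$TA[i1[j]], TA2 = sl$TA[j], delta = delta[j])
}
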