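#' Sample leisure durations from a solved policy
#'
#' Inverse-CDF sampling from the gridded density: the cumulative trapezoid
#' of the density is linearly interpolated and inverted at uniform draws.
#' Point policies return their atom.  Reproducible for a fixed seed.
#'
#' @param policy A `solved_policy` (or `policy_density`).
#' @param n Number of draws (`>= 1`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of durations in `[0, tau_max]`.
#' @export
sample_leisure <- function(policy, n, seed = NULL) {
  stopifnot(inherits(policy, "policy_density"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.na(policy$atom)) return(rep(policy$atom, n))
  cdf <- cumtrapz(policy$tau, policy$density)
  total <- cdf[length(cdf)]
  if (abs(total - 1) > 1e-6) stop_domain("policy density is not normalized.")
  cdf <- cdf / total
  u <- stats::runif(n)
  # invert the piecewise-linear CDF; duplicated knots (zero-density stretches)
  # are collapsed to keep approx() strictly monotone
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], policy$tau[keep], xout = u, rule = 2)$y
}

#' Simulate one trial as an ethogram
#'
#' Starting in the post-reward state, the subject alternates a sampled
#' leisure bout with a price-long work bout; each completed work bout ends
#' with a reward event.  Bouts tile `[0, T]` exactly; the final bout is
#' truncated at the trial end and counted pro-rata.  (Starting with a work
#' bout instead is available via `start_with`.)
#'
#' @param task A [task_spec()] (supplies `P` and the trial duration `T`).
#' @param policy A `solved_policy` for that task.
#' @param seed Integer seed for reproducibility.
#' @param trial_id Identifier stored with the bouts.
#' @param start_with `"leisure"` (post-reward start, the default) or
#'   `"work"`.
#' @return A tibble of class `ethogram` with columns `trial_id`,
#'   `bout_index`, `kind` (`"work"`/`"leisure"`), `onset_s`, `duration_s`,
#'   and attributes `reward_times` (seconds) and `T_trial`, `P`.
#' @export
simulate_trial <- function(task, policy, seed = NULL, trial_id = 1L,
                           start_with = c("leisure", "work")) {
  stopifnot(inherits(task, "task_spec"))
  start_with <- match.arg(start_with)
  if (!is.null(seed)) set.seed(seed)
  T_trial <- task$T_trial
  P <- task$P

  kind <- character()
  onset <- numeric()
  duration <- numeric()
  reward_times <- numeric()
  t <- 0
  next_kind <- start_with
  while (t < T_trial) {
    if (next_kind == "leisure") {
      len <- sample_leisure(policy, 1L)
      next_kind <- "work"
    } else {
      len <- P
      next_kind <- "leisure"
    }
    full <- t + len <= T_trial
    len_used <- min(len, T_trial - t)
    if (len_used > 0) {
      kind <- c(kind, if (next_kind == "leisure") "work" else "leisure")
      onset <- c(onset, t)
      duration <- c(duration, len_used)
      if (kind[length(kind)] == "work" && full) {
        reward_times <- c(reward_times, t + len_used)
      }
    }
    t <- t + len_used
    if (len_used < len) break  # truncated final bout
  }
  out <- tibble::tibble(
    trial_id = as.integer(trial_id),
    bout_index = seq_along(kind),
    kind = kind, onset_s = onset, duration_s = duration
  )
  attr(out, "reward_times") <- reward_times
  attr(out, "T_trial") <- T_trial
  attr(out, "P") <- P
  class(out) <- c("ethogram", class(out))
  out
}

#' Simulate many trials
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of trials.
#' @param seed Base seed; trial `i` uses `seed + i - 1`.
#' @return A tibble binding the per-trial ethograms (class `ethogram_set`),
#'   with a `rewards` attribute: tibble of (`trial_id`, `time_s`).
#' @export
simulate_trials <- function(task, policy, n_trials, seed = 1L) {
  trials <- purrr::map(seq_len(n_trials), function(i) {
    simulate_trial(task, policy, seed = seed + i - 1L, trial_id = i)
  })
  rewards <- purrr::map_dfr(trials, function(e) {
    tibble::tibble(trial_id = e$trial_id[1] %||% integer(),
                   time_s = attr(e, "reward_times"))
  })
  out <- dplyr::bind_rows(trials)
  attr(out, "rewards") <- rewards
  attr(out, "T_trial") <- task$T_trial
  attr(out, "P") <- task$P
  class(out) <- c("ethogram_set", class(out))
  out
}

#' Empirical time allocation of an ethogram
#'
#' Total work time divided by trial duration (per trial for multi-trial
#' sets).
#'
#' @param e An ethogram tibble from [simulate_trial()] or
#'   [simulate_trials()].
#' @return A single TA for one trial, or a tibble (`trial_id`, `TA`) for a
#'   set.
#' @export
empirical_ta <- function(e) {
  T_trial <- attr(e, "T_trial")
  if (is.null(T_trial)) stop_domain("not an ethogram: missing trial length.")
  per <- dplyr::summarise(
    dplyr::group_by(e, .data$trial_id),
    TA = sum(.data$duration_s[.data$kind == "work"]) / T_trial,
    .groups = "drop"
  )
  if (inherits(e, "ethogram_set")) per else per$TA[[1]]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
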