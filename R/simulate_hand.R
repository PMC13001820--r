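#' Simulate a hand reach at 1000 Hz
#'
#' The hand rests at the start position (plus measurement noise) until the
#' go cue plus the reaction time, then moves 20 cm (by default) straight
#' ahead to the target along a minimum-jerk displacement profile, and rests
#' at the target afterwards. Used for the two reach conditions; for the
#' passive conditions call with `rt = NULL` to keep the hand at the start
#' throughout.
#'
#' @param schedule One-row tibble from [event_schedule()]; `t_trial_end` may
#'   still be `NA` (the recording is then sized from the kinematics).
#' @param rt Hand reaction time, s (onset at `t_go + rt`). Values below
#'   0.1 s are allowed deliberately, to build exclusion fixtures. `NULL`
#'   simulates a stationary hand.
#' @param d Movement duration, s (default 1.36).
#' @param a Movement amplitude, cm (default 20).
#' @param noise_sd Measurement-noise SD, cm (default 0.002; the
#'   manipulandum's position signal is nearly noise-free).
#' @param seed Integer seed or `NULL` (use the caller's RNG).
#' @param t_record_from,t_record_to Recording span, s.
#' @return A list: `hand` (tibble `time`, `x`, `y` at 1000 Hz) and `truth`
#'   (list `t_onset`, `t_offset`, `rt`, `duration`, `peak_velocity`;
#'   all `NULL`-safe for stationary hands).
#' @export
simulate_hand_reach <- function(schedule, rt, d = 1.36, a = 20,
                                noise_sd = 0.002, seed = NULL,
                                t_record_from = NULL, t_record_to = NULL) {
  local_seed(seed, {
    stopifnot(is.data.frame(schedule), nrow(schedule) == 1L)
    geom <- geometry_config()
    t_go <- schedule$t_go
    t0 <- t_record_from %||% (schedule$t_show_target - 1)
    default_end <- if (is.null(rt)) {
      t_go + 2.5
    } else {
      t_go + rt + d + 1.5
    }
    t1 <- t_record_to %||%
      (if (is.finite(schedule$t_trial_end)) schedule$t_trial_end + 1
       else default_end)
    t <- time_grid(t0, t1, 1000)
    n <- length(t)
    x <- rep(geom$start_position[1], n)
    y <- rep(geom$start_position[2], n)
    truth <- list(t_onset = NULL, t_offset = NULL, rt = NULL,
                  duration = NULL, peak_velocity = NULL)
    if (!is.null(rt)) {
      if (d <= 0) stop("`d` must be positive.", call. = FALSE)
      t_on <- t_go + rt
      u <- mj_step((t - t_on) / d)
      y <- y + a * u
      truth <- list(t_onset = t_on, t_offset = t_on + d, rt = rt,
                    duration = d, peak_velocity = 1.875 * a / d)
    }
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd)
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    list(hand = tibble::tibble(time = t, x = x, y = y), truth = truth)
  })
}

# Condition-specific trial end on the *noiseless* kinematics, used by the
# simulator to size the recording. The analysis recomputes ends from data.
scheduled_trial_end <- function(condition, t_go, post_cue_delay,
                                cursor_move_duration = NA, rt = NA, d = NA,
                                a = 20, target_radius = 1) {
  switch(condition,
    cue_monitoring = t_go + post_cue_delay + 0.8,
    cursor_tracking = t_go + post_cue_delay + cursor_move_duration,
    reach_visible = {
      # cursor enters the target disc when the remaining distance equals
      # the target radius, then must dwell 500 ms
      tau_in <- stats::uniroot(function(u) a * mj_step(u) - (a - target_radius),
                               c(0.5, 1), tol = 1e-10)$root
      t_go + rt + d * tau_in + 0.5
    },
    reach_invisible = {
      # hand speed falls below 10 cm/s for 200 ms after the peak
      tau_slow <- stats::uniroot(function(u) {
        30 * u^2 * (1 - u)^2 - 10 * d / a
      }, c(0.5, 1), tol = 1e-10)$root
      t_go + rt + d * tau_slow + 0.2
    },
    stop("unknown condition", call. = FALSE)
  )
}
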