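#' Simulate fixational gaze with injected microsaccades
#'
#' Generates a 500-Hz gaze trace for one trial together with its ground
#' truth. The trace emulates what a video eye tracker records while a
#' participant acquires and then holds fixation on the reach target:
#'
#' * gaze rests near the hand start position until shortly after the target
#'   appears, then a single acquisition saccade (smooth sigmoidal step,
#'   50 ms) lands near the target;
#' * fixational drift is a zero-mean random walk reflected at about 1 cm
#'   from the current fixation centre, plus white measurement noise;
#' * microsaccade onsets are drawn from an inhomogeneous point process whose
#'   rate follows `rate_profile` (time relative to the go cue); each event is
#'   a smooth step displacement of the drawn amplitude over the drawn
#'   duration, so peak velocity grows with amplitude (main-sequence-like,
#'   peak speed `1.875 * amplitude / duration`);
#' * optional blinks (runs of missing samples) and instructed violations
#'   (late fixation start, early fixation end, far saccade landing) exercise
#'   the exclusion rules downstream.
#'
#' @param schedule One-row tibble from [event_schedule()] with a finite
#'   `t_trial_end`.
#' @param rate_profile A profile from [rate_constant()],
#'   [rate_linear_ramp()] or [rate_piecewise_task()].
#' @param noise_sd White measurement-noise SD, cm (default 0.005).
#' @param seed Integer seed; the function is a pure function of its
#'   arguments and the seed. `NULL` uses (and advances) the caller's RNG.
#' @param drift_step Random-walk step SD per 500-Hz sample, cm
#'   (default 0.001).
#' @param fix_latency Acquisition-saccade onset after target appearance,
#'   seconds (default 0.04; `>= 0.1` creates a late-fixation violation).
#' @param landing_offset Acquisition landing error, cm `c(x, y)` relative to
#'   the target centre; `NULL` draws a small random error (SD 0.3 cm).
#' @param depart_at If non-`NULL`, time (s) at which gaze saccades 8 cm away
#'   from the target and stays there (early-fixation-end fixture).
#' @param excursion_at If non-`NULL`, time (s) at which gaze makes a large
#'   out-and-back excursion: a saccade landing `excursion_dist` cm from the
#'   target, a 100-ms dwell, and a return saccade (far-landing fixture).
#' @param excursion_dist Excursion landing distance from the target, cm
#'   (default 7).
#' @param blink_at,blink_duration If non-`NULL`, a run of missing samples
#'   starting at `blink_at` lasting `blink_duration` s (default 0.15).
#' @param amp_mean,amp_sd,amp_range Microsaccade amplitude distribution:
#'   normal, truncated to `amp_range` (cm). Defaults 0.95, 0.25,
#'   `c(0.3, 1.8)`, matching typical fixational microsaccades of this size
#'   regime.
#' @param dur_mean,dur_sd,dur_range Event duration distribution (s),
#'   truncated normal; defaults 0.086, 0.015, `c(0.05, 0.13)`.
#' @param t_record_from,t_record_to Recording span (s); defaults 1 s before
#'   target appearance to 1 s after trial end.
#' @return A list with elements `gaze` (tibble: `time`, `x`, `y`; `NA` for
#'   missing samples), `events` (tibble of injected microsaccades:
#'   `t_onset`, `t_offset`, `duration`, `amplitude`, `peak_velocity`,
#'   `direction`), and `fixation` (list: `t_fix_start`, `landing_offset`).
#' @export
simulate_fixational_gaze <- function(schedule, rate_profile,
                                     noise_sd = 0.005, seed = NULL,
                                     drift_step = 0.001,
                                     fix_latency = 0.04,
                                     landing_offset = NULL,
                                     depart_at = NULL,
                                     excursion_at = NULL,
                                     excursion_dist = 7,
                                     blink_at = NULL, blink_duration = 0.15,
                                     amp_mean = 0.95, amp_sd = 0.25,
                                     amp_range = c(0.3, 1.8),
                                     dur_mean = 0.086, dur_sd = 0.015,
                                     dur_range = c(0.05, 0.13),
                                     t_record_from = NULL,
                                     t_record_to = NULL) {
  local_seed(seed, {
    stopifnot(is.data.frame(schedule), nrow(schedule) == 1L)
    if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
    if (!is.finite(schedule$t_trial_end)) {
      stop("`schedule$t_trial_end` must be set before simulating gaze.",
           call. = FALSE)
    }
    geom <- geometry_config()
    t_show <- schedule$t_show_target
    t_go <- schedule$t_go
    t_end <- schedule$t_trial_end
    t0 <- t_record_from %||% (t_show - 1)
    t1 <- t_record_to %||% (t_end + 1)
    t <- time_grid(t0, t1, 500)
    n <- length(t)

    if (is.null(landing_offset)) {
      landing_offset <- stats::rnorm(2, 0, 0.3)
    }
    t_fix <- t_show + fix_latency
    acq_dur <- 0.05
    t_fix_start <- t_fix + acq_dur  # landing = fixation established

    # piecewise fixation-centre path: start -> target + landing error
    centre_x <- rep(geom$start_position[1], n)
    centre_y <- rep(geom$start_position[2], n)
    acq_vec <- geom$target_position + landing_offset - geom$start_position
    u <- mj_step((t - t_fix) / acq_dur)
    centre_x <- centre_x + acq_vec[1] * u
    centre_y <- centre_y + acq_vec[2] * u

    # injected microsaccades between fixation start and trial end
    events <- draw_microsaccades(
      t_from = max(t_fix_start, t_show), t_to = t_end,
      rate_fn = function(tt) rate_profile$rate_fn(tt - t_go),
      amp_mean = amp_mean, amp_sd = amp_sd, amp_range = amp_range,
      dur_mean = dur_mean, dur_sd = dur_sd, dur_range = dur_range
    )
    if (nrow(events) > 0) {
      # directions: uniform, but re-aim toward the target once the
      # accumulated offset exceeds 1.5 cm, so gaze stays on target
      off <- c(0, 0)
      dirs <- numeric(nrow(events))
      for (k in seq_len(nrow(events))) {
        if (sqrt(sum(off^2)) > 1.5) {
          back <- atan2(-off[2], -off[1])
          dirs[k] <- back + stats::runif(1, -pi / 6, pi / 6)
        } else {
          dirs[k] <- stats::runif(1, 0, 2 * pi)
        }
        off <- off + events$amplitude[k] * c(cos(dirs[k]), sin(dirs[k]))
      }
      events$direction <- dirs
      for (k in seq_len(nrow(events))) {
        uu <- mj_step((t - events$t_onset[k]) / events$duration[k])
        centre_x <- centre_x + events$amplitude[k] * cos(dirs[k]) * uu
        centre_y <- centre_y + events$amplitude[k] * sin(dirs[k]) * uu
      }
    }

    # optional early departure from the target (exclusion fixture)
    if (!is.null(depart_at)) {
      uu <- mj_step((t - depart_at) / 0.05)
      centre_y <- centre_y + 8 * uu
    }

    # optional out-and-back excursion landing beyond 6 cm (exclusion fixture)
    if (!is.null(excursion_at)) {
      out <- mj_step((t - excursion_at) / 0.05)
      back <- mj_step((t - (excursion_at + 0.15)) / 0.05)
      centre_x <- centre_x + excursion_dist * (out - back)
    }

    # bounded fixational drift + white measurement noise
    bound <- 1 / sqrt(2)
    drift_x <- fold_reflect(cumsum(stats::rnorm(n, 0, drift_step)), bound)
    drift_y <- fold_reflect(cumsum(stats::rnorm(n, 0, drift_step)), bound)
    x <- centre_x + drift_x + stats::rnorm(n, 0, noise_sd)
    y <- centre_y + drift_y + stats::rnorm(n, 0, noise_sd)

    if (!is.null(blink_at)) {
      bad <- t >= blink_at & t < blink_at + blink_duration
      x[bad] <- NA_real_
      y[bad] <- NA_real_
    }

    list(
      gaze = tibble::tibble(time = t, x = x, y = y),
      events = events,
      fixation = list(t_fix_start = t_fix_start,
                      landing_offset = landing_offset)
    )
  })
}

# Draw non-overlapping microsaccade events from an inhomogeneous point
# process by thinning; rate_fn takes absolute trial time.
draw_microsaccades <- function(t_from, t_to, rate_fn,
                               amp_mean, amp_sd, amp_range,
                               dur_mean, dur_sd, dur_range,
                               min_gap = 0.05) {
  empty <- tibble::tibble(
    t_onset = numeric(), t_offset = numeric(), duration = numeric(),
    amplitude = numeric(), peak_velocity = numeric(), direction = numeric()
  )
  span <- t_to - t_from
  if (span <= 0) return(empty)
  grid <- seq(t_from, t_to, length.out = 512)
  r <- rate_fn(grid)
  if (any(r < 0)) stop("Rate profile is negative inside the trial window.",
                       call. = FALSE)
  rmax <- max(r)
  if (rmax <= 0) return(empty)
  # dead-time compensation: each accepted event blocks ~(mean duration +
  # min_gap) of the timeline, so thin with the inflated intensity
  # r / (1 - r * block); the realised onset rate then matches the profile
  block <- dur_mean + min_gap
  inflate <- function(r) r / pmax(1 - pmin(r * block, 0.8), 0.2)
  rmax <- inflate(rmax)
  n_cand <- stats::rpois(1, rmax * span)
  if (n_cand == 0) return(empty)
  cand <- sort(stats::runif(n_cand, t_from, t_to))
  keep <- stats::runif(n_cand) < inflate(rate_fn(cand)) / rmax
  onsets <- cand[keep]
  if (length(onsets) == 0) return(empty)
  rtrunc <- function(n, mean, sd, range) {
    pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
  }
  dur <- rtrunc(length(onsets), dur_mean, dur_sd, dur_range)
  amp <- rtrunc(length(onsets), amp_mean, amp_sd, amp_range)
  # enforce non-overlap (with a small gap) and containment in the window
  ok <- logical(length(onsets))
  last_end <- -Inf
  for (k in seq_along(onsets)) {
    if (onsets[k] >= last_end + min_gap &&
        onsets[k] + dur[k] <= t_to) {
      ok[k] <- TRUE
      last_end <- onsets[k] + dur[k]
    }
  }
  tibble::tibble(
    t_onset = onsets[ok],
    t_offset = onsets[ok] + dur[ok],
    duration = dur[ok],
    amplitude = amp[ok],
    peak_velocity = 1.875 * amp[ok] / dur[ok],
    direction = NA_real_
  )
}
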