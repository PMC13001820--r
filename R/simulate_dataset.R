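#' Simulator configuration
#'
#' Bundles every tunable of the synthetic four-condition dataset. Defaults
#' reproduce the task's study conditions: a 20-cm reach geometry, delays of
#' 1.8--2.0 s, a 0.3-s post-cue delay, cursor movements of 1.15--1.35 s with
#' a 0.25-cm lateral bow, reach reaction-time medians of 0.38 s (visible
#' cursor) and 0.45 s (invisible), mean reach duration 1.36 s, and a
#' task-like microsaccade-rate profile ([rate_piecewise_task()]).
#'
#' @param rate_profile Microsaccade-rate profile (see [rate_profiles]).
#' @param noise_sd,drift_step Gaze measurement-noise SD (cm) and drift step
#'   SD per 500-Hz sample (cm); see [simulate_fixational_gaze()].
#' @param hand_noise_sd Hand measurement-noise SD, cm.
#' @param rt_median Named reaction-time medians (s) for `reach_visible` and
#'   `reach_invisible`.
#' @param rt_shift,rt_sdlog Shift (s) and log-SD of the shifted log-normal
#'   reaction-time distribution.
#' @param reach_duration_mean,reach_duration_sd Reach-duration distribution
#'   (s), truncated to `[1.1, 1.6]`.
#' @param participant_rate_sd Log-SD of the per-participant multiplicative
#'   factor on the microsaccade-rate profile (default 0.1).
#' @param violation_fractions Named fractions of trials planted to violate
#'   each exclusion rule (`rt_below_100ms_or_missing_eye`,
#'   `fixation_start_late`, `fixation_end_early`, `landing_gt_6cm`);
#'   all 0 by default.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(rate_profile = rate_piecewise_task(),
                       noise_sd = 0.005, drift_step = 0.001,
                       hand_noise_sd = 0.002,
                       rt_median = c(reach_visible = 0.38,
                                     reach_invisible = 0.45),
                       rt_shift = 0.15, rt_sdlog = 0.2,
                       reach_duration_mean = 1.36,
                       reach_duration_sd = 0.08,
                       participant_rate_sd = 0.1,
                       violation_fractions = c(
                         rt_below_100ms_or_missing_eye = 0,
                         fixation_start_late = 0,
                         fixation_end_early = 0,
                         landing_gt_6cm = 0)) {
  cfg <- list(
    rate_profile = rate_profile, noise_sd = noise_sd,
    drift_step = drift_step, hand_noise_sd = hand_noise_sd,
    rt_median = rt_median, rt_shift = rt_shift, rt_sdlog = rt_sdlog,
    reach_duration_mean = reach_duration_mean,
    reach_duration_sd = reach_duration_sd,
    participant_rate_sd = participant_rate_sd,
    violation_fractions = violation_fractions
  )
  class(cfg) <- "sim_config"
  cfg
}

exclusion_rules <- function() {
  c("rt_below_100ms_or_missing_eye", "fixation_start_late",
    "fixation_end_early", "landing_gt_6cm")
}

#' Generate a synthetic four-condition dataset
#'
#' Simulates `n_participants` participants, each performing
#' `n_trials_per_condition` trials in the four task conditions, with
#' ground-truth microsaccades, kinematic landmarks and (optionally) planted
#' exclusion-rule violations. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param n_participants Number of participants (default 17).
#' @param n_trials_per_condition Trials per condition per participant
#'   (default 60, i.e. 240 per participant).
#' @param seed Integer seed.
#' @return A tibble with one row per trial: identifiers (`participant`,
#'   `condition`, `trial`), the event schedule (`t_show_target`, `t_go`,
#'   `t_trial_end`, `post_cue_delay`, `cursor_move_duration`), the planted
#'   `violation` (`"none"` or a rule name), ground-truth kinematics
#'   (`rt_true`, `move_duration_true`, `hand_onset_true`,
#'   `hand_offset_true`, `t_fix_start_true`), and list-columns `gaze`
#'   (500 Hz), `hand` (1000 Hz), `cursor` (1000 Hz or `NULL`) and
#'   `events_true` (injected microsaccades). The `sim_config` used is
#'   attached as an attribute.
#' @examples
#' ds <- generate_dataset(n_participants = 1, n_trials_per_condition = 2,
#'                        seed = 1)
#' dplyr::count(ds, condition)
#' @export
generate_dataset <- function(config = sim_config(), n_participants = 17,
                             n_trials_per_condition = 60, seed = 1) {
  stopifnot(inherits(config, "sim_config"),
            n_participants >= 1, n_trials_per_condition >= 1)
  local_seed(seed, {
    geom <- geometry_config()
    conds <- task_conditions()
    rows <- vector("list", n_participants * length(conds) *
                     n_trials_per_condition)
    i <- 0L
    for (p in seq_len(n_participants)) {
      pid <- sprintf("P%02d", p)
      pfac <- exp(stats::rnorm(1, 0, config$participant_rate_sd))
      base_fn <- config$rate_profile$rate_fn
      prof_p <- new_rate_profile(
        config$rate_profile$name, config$rate_profile$params,
        function(tt) pfac * base_fn(tt)
      )
      # bind pfac/base_fn per participant
      environment(prof_p$rate_fn) <- list2env(
        list(pfac = pfac, base_fn = base_fn), parent = baseenv())
      for (cond in conds) {
        for (tr in seq_len(n_trials_per_condition)) {
          i <- i + 1L
          rows[[i]] <- simulate_trial(pid, cond, tr, config, prof_p, geom)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "sim_config") <- config
    out
  })
}

# One trial; uses the caller's RNG stream.
simulate_trial <- function(pid, cond, tr, config, profile, geom) {
  delay <- stats::runif(1, 1.8, 2.0)
  cursor_d <- if (cond == "cursor_tracking") stats::runif(1, 1.15, 1.35) else 1.25
  sched <- event_schedule(cond, delay_duration = delay,
                          cursor_move_duration = cursor_d)

  # planted violation: first success in the rules' listed order
  vf <- config$violation_fractions
  violation <- "none"
  for (rule in exclusion_rules()) {
    p_rule <- vf[[rule]] %||% 0
    # passive conditions have no reaction time; their rule-1 violations are
    # planted as missing eye data below
    if (stats::runif(1) < p_rule) {
      violation <- rule
      break
    }
  }

  # reaction time and movement duration (reach conditions)
  rt <- NA_real_
  move_d <- NA_real_
  if (cond %in% c("reach_visible", "reach_invisible")) {
    med <- config$rt_median[[cond]]
    rt <- config$rt_shift +
      stats::rlnorm(1, log(med - config$rt_shift), config$rt_sdlog)
    if (violation == "rt_below_100ms_or_missing_eye" &&
        stats::runif(1) < 0.5) {
      # fast-RT variant of rule 1; planted well below 100 ms so that the
      # *measured* RT (true RT + the ~5.9%-of-duration onset-criterion
      # lag) still falls below the rule's threshold unambiguously
      rt <- stats::runif(1, 0.004, 0.015)
    }
    move_d <- pmin(pmax(stats::rnorm(1, config$reach_duration_mean,
                                     config$reach_duration_sd), 1.1), 1.6)
  }
  rt_fast <- violation == "rt_below_100ms_or_missing_eye" &&
    !is.na(rt) && rt < 0.1

  sched$t_trial_end <- scheduled_trial_end(
    cond, sched$t_go, sched$post_cue_delay,
    cursor_move_duration = cursor_d, rt = rt, d = move_d,
    a = geom$target_position[2], target_radius = geom$target_diameter / 2
  )

  # gaze, with violation knobs
  blink_at <- if (violation == "rt_below_100ms_or_missing_eye" && !rt_fast)
    sched$t_go - 0.5 else NULL
  fix_latency <- if (violation == "fixation_start_late")
    stats::runif(1, 0.15, 0.30) else 0.04
  depart_at <- if (violation == "fixation_end_early")
    sched$t_trial_end - stats::runif(1, 0.2, 0.4) else NULL
  excursion_at <- if (violation == "landing_gt_6cm")
    sched$t_go - 1.0 else NULL

  g <- simulate_fixational_gaze(
    sched, profile, noise_sd = config$noise_sd, seed = NULL,
    drift_step = config$drift_step, fix_latency = fix_latency,
    depart_at = depart_at, blink_at = blink_at,
    excursion_at = excursion_at
  )

  # hand and cursor
  h <- simulate_hand_reach(
    sched, rt = if (cond %in% c("reach_visible", "reach_invisible")) rt else NULL,
    d = if (is.na(move_d)) 1.36 else move_d,
    a = geom$target_position[2],
    noise_sd = config$hand_noise_sd, seed = NULL
  )
  cursor <- switch(cond,
    cue_monitoring = h$hand,
    reach_visible = h$hand,
    reach_invisible = NULL,
    cursor_tracking = {
      traj <- generate_cursor_trajectory(
        a = geom$target_position[2], d = cursor_d,
        bow_direction = if (stats::runif(1) < 0.5) "left" else "right"
      )
      tt <- h$hand$time
      t_move <- sched$t_go + sched$post_cue_delay
      cx <- stats::approx(traj$time + t_move, traj$x, xout = tt,
                          yleft = 0, yright = 0)$y
      cy <- stats::approx(traj$time + t_move, traj$y, xout = tt,
                          yleft = 0,
                          yright = geom$target_position[2])$y
      tibble::tibble(time = tt, x = cx, y = cy)
    }
  )

  tibble::tibble(
    participant = pid, condition = cond, trial = tr,
    t_show_target = sched$t_show_target, t_go = sched$t_go,
    t_trial_end = sched$t_trial_end,
    post_cue_delay = sched$post_cue_delay,
    cursor_move_duration = sched$cursor_move_duration,
    violation = violation,
    rt_true = rt, move_duration_true = move_d,
    hand_onset_true = h$truth$t_onset %||% NA_real_,
    hand_offset_true = h$truth$t_offset %||% NA_real_,
    t_fix_start_true = g$fixation$t_fix_start,
    gaze = list(g$gaze), hand = list(h$hand),
    cursor = list(cursor), events_true = list(g$events)
  )
}
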