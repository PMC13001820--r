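#' Run the per-trial analysis stages
#'
#' For every trial: upsample the gaze recording to 1000 Hz, low-pass filter
#' it (15 Hz, zero phase), detect microsaccades with the elliptic
#' median-SD velocity criterion inside `[t_show_target, t_trial_end]`;
#' filter the hand recording (10 Hz, zero phase), segment the reach with
#' the 5%-of-peak criteria (reach conditions), and recompute the
#' condition-specific trial end from the data (cursor-in-target dwell for
#' visible reaches, hand-stillness rule for invisible reaches, the
#' scheduled interval for the passive conditions). Also derives the
#' fixation landmarks and flags needed by [apply_exclusions()].
#'
#' @param dataset A trial tibble from [generate_dataset()] or
#'   [read_trials()].
#' @param lambda Detection-threshold multiplier (default 5).
#' @param min_duration Minimum microsaccade duration, s (default 0.040).
#' @param max_fix_dist Fixation radius around the target used for the
#'   fixation landmarks, cm (default 6).
#' @return The input tibble with added columns: list-column `events`
#'   (detected microsaccades with amplitude and landing), `eye_missing`,
#'   `t_fix_start`, `t_fix_end`, `t_window_start`, `t_window_end`,
#'   `landing_max_dist`, `reaction_time`, `move_duration`,
#'   `hand_peak_velocity`, `mid_range_speed`, `t_move_start`, `t_move_end`.
#' @export
analyze_trials <- function(dataset, lambda = 5, min_duration = 0.040,
                           max_fix_dist = 6) {
  geom <- geometry_config()
  target <- geom$target_position
  out <- vector("list", nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    row <- dataset[i, ]
    out[[i]] <- analyze_one_trial(row, lambda, min_duration, max_fix_dist,
                                  target)
  }
  dplyr::bind_cols(dataset, dplyr::bind_rows(out))
}

analyze_one_trial <- function(row, lambda, min_duration, max_fix_dist,
                              target) {
  t_show <- row$t_show_target
  t_go <- row$t_go
  cond <- row$condition

  # ---- hand stream: filter, differentiate, segment (reach conditions)
  hand <- row$hand[[1]]
  hand_f <- filter_hand(hand)
  hand_v <- differentiate(hand_f, order = 1)
  speed <- tibble::tibble(time = hand_v$time,
                          speed = sqrt(hand_v$x^2 + hand_v$y^2))
  seg <- NULL
  if (cond %in% c("reach_visible", "reach_invisible")) {
    seg <- tryCatch(find_movement_onset_offset(speed, t_from = t_go),
                    error = function(e) NULL)
  }

  # ---- condition-specific trial end, recomputed from the data
  t_end <- switch(cond,
    cue_monitoring = t_go + row$post_cue_delay + 0.8,
    cursor_tracking = t_go + row$post_cue_delay + row$cursor_move_duration,
    reach_visible = tryCatch(
      trial_end_reach_visible(row$cursor[[1]], target,
                              target_radius = 1, t_from = t_go),
      error = function(e) row$t_trial_end),
    reach_invisible = tryCatch(
      trial_end_reach_invisible(speed, t_onset = seg$t_onset),
      error = function(e) row$t_trial_end)
  )

  # ---- movement phase for the movement zone
  move <- switch(cond,
    cue_monitoring = c(t_go + row$post_cue_delay,
                       t_go + row$post_cue_delay + 0.8),
    cursor_tracking = c(t_go + row$post_cue_delay,
                        t_go + row$post_cue_delay +
                          row$cursor_move_duration),
    c(if (is.null(seg)) NA_real_ else seg$t_onset,
      if (is.null(seg)) NA_real_ else seg$t_offset)
  )

  # ---- gaze stream: upsample, filter, detect
  gaze <- row$gaze[[1]]
  eye_missing <- any(is.na(gaze$x[gaze$time >= t_show &
                                    gaze$time <= t_end]))
  gaze_up <- upsample_eye(gaze)
  gaze_f <- filter_eye(gaze_up)
  vel <- detection_velocity(gaze_f)
  events <- tryCatch(
    detect_microsaccades(vel, min_duration = min_duration, lambda = lambda,
                         t_from = t_show, t_to = t_end, pos = gaze_f),
    error = function(e) {
      tibble::tibble(t_onset = numeric(), t_offset = numeric(),
                     duration = numeric(), peak_velocity = numeric(),
                     amplitude = numeric(), x_land = numeric(),
                     y_land = numeric())
    })
  landing_max <- if (nrow(events)) {
    max(sqrt((events$x_land - target[1])^2 +
               (events$y_land - target[2])^2))
  } else NA_real_

  # ---- fixation landmarks within [t_show, t_end]
  win <- gaze_f$time >= t_show & gaze_f$time <= t_end
  dist <- sqrt((gaze_f$x[win] - target[1])^2 +
                 (gaze_f$y[win] - target[2])^2)
  tw <- gaze_f$time[win]
  infix <- !is.na(dist) & dist <= max_fix_dist
  t_fix_start <- if (any(infix)) tw[which(infix)[1]] else NA_real_
  t_fix_end <- if (any(infix)) tw[max(which(infix))] else NA_real_

  mrs <- if (cond %in% c("reach_visible", "reach_invisible")) {
    tryCatch(mid_range_avg_speed(hand_f), error = function(e) NA_real_)
  } else NA_real_

  tibble::tibble(
    events = list(events),
    eye_missing = eye_missing,
    t_fix_start = t_fix_start, t_fix_end = t_fix_end,
    t_window_start = t_show, t_window_end = t_end,
    landing_max_dist = landing_max,
    reaction_time = if (is.null(seg)) NA_real_ else seg$t_onset - t_go,
    move_duration = if (is.null(seg)) NA_real_ else seg$duration,
    hand_peak_velocity = if (is.null(seg)) NA_real_ else seg$peak_velocity,
    mid_range_speed = mrs,
    t_move_start = move[1], t_move_end = move[2]
  )
}

#' Per participant-condition zone summaries
#'
#' Estimates each participant-condition rate time course (state-based or
#' causal-kernel method), averages it over the fixed analysis zones, and
#' appends the per-trial-normalised movement-zone rate, yielding the table
#' the condition-level statistics run on.
#'
#' @param analyzed Retained trials from [analyze_trials()] (after
#'   exclusion), with the detected `events` list-column.
#' @param method `"state_based"` or `"causal_kernel"`.
#' @param zones Zone names to include (default all fixed zones from
#'   [zone_definitions()]).
#' @param alpha Kernel parameter for the causal-kernel method, 1/s.
#' @param mean_event_duration Mean microsaccade duration for the state
#'   method, s; `NULL` uses the dataset's own mean detected duration.
#' @param include_movement_zone Append the movement zone (default TRUE;
#'   the cue-monitoring condition is conventionally dropped from
#'   movement-zone statistics, but its value is still reported here).
#' @return A tibble `participant`, `condition`, `zone`, `mean_rate` (Hz).
#' @export
zone_summaries <- function(analyzed,
                           method = c("state_based", "causal_kernel"),
                           zones = NULL, alpha = 1 / 0.05,
                           mean_event_duration = NULL,
                           include_movement_zone = TRUE) {
  method <- match.arg(method)
  if (is.null(zones)) zones <- zone_definitions()$zone
  if (is.null(mean_event_duration) && method == "state_based") {
    durs <- unlist(lapply(analyzed$events, function(e) {
      if (nrow(e)) e$t_offset - e$t_onset else numeric()
    }))
    mean_event_duration <- if (length(durs)) mean(durs) else 0.08
  }
  groups <- dplyr::distinct(analyzed, .data$participant, .data$condition)
  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    sub <- analyzed[analyzed$participant == groups$participant[g] &
                      analyzed$condition == groups$condition[g], ]
    series <- if (method == "state_based") {
      rate_state_method(sub, mean_event_duration = mean_event_duration)
    } else {
      rate_kernel_method(sub, alpha = alpha)
    }
    vals <- vapply(zones, function(z) zone_average(series, z), numeric(1))
    res <- tibble::tibble(
      participant = groups$participant[g],
      condition = groups$condition[g],
      zone = zones, mean_rate = vals
    )
    if (include_movement_zone) {
      mv <- sub[!is.na(sub$t_move_start) & !is.na(sub$t_move_end), ]
      if (nrow(mv)) {
        res <- dplyr::bind_rows(res, tibble::tibble(
          participant = groups$participant[g],
          condition = groups$condition[g],
          zone = "movement", mean_rate = movement_zone_rate(mv)
        ))
      }
    }
    res
  })
}

#' Condition-level statistics on a zone-summary table
#'
#' Reproduces the statistical design of the analysis: a 2 x 4
#' repeated-measures ANOVA over the initial-fixation and pre-cue zones by
#' the four conditions; separate one-way rm-ANOVAs over conditions within
#' each requested zone (with Holm post hoc letter groupings); a 2 x 4
#' rm-ANOVA contrasting the narrow pre- and post-cue inhibition zones; and
#' a paired t-test of hand reaction time between the two reach conditions.
#'
#' @param zone_tab Tibble from [zone_summaries()].
#' @param rt_tab Optional tibble `participant`, `condition`,
#'   `reaction_time` (means per participant for the two reach conditions).
#' @param pre_cue_zone Which pre-cue zone feeds the 2 x 4 ANOVA
#'   (default `"pre_cue_250"`).
#' @param correction Post hoc correction passed to [posthoc_pairwise()].
#' @return A list: `zone_by_condition` (rm_anova), `one_way` (named list
#'   of rm_anova per zone), `posthoc` (named list per zone),
#'   `cue_inhibition` (rm_anova) and `rt_test` (tibble or NULL).
#' @export
condition_stats <- function(zone_tab, rt_tab = NULL,
                            pre_cue_zone = "pre_cue_250",
                            correction = "holm") {
  two_zones <- zone_tab[zone_tab$zone %in%
                          c("initial_fixation", pre_cue_zone), ]
  zone_by_condition <- rm_anova(two_zones, "mean_rate",
                                c("zone", "condition"))
  one_zones <- c("initial_fixation", pre_cue_zone, "post_inhibition",
                 "movement")
  one_zones <- intersect(one_zones, unique(zone_tab$zone))
  one_way <- list()
  posthoc <- list()
  for (z in one_zones) {
    sub <- zone_tab[zone_tab$zone == z, ]
    if (z == "movement") {
      sub <- sub[sub$condition != "cue_monitoring", ]
    }
    one_way[[z]] <- rm_anova(sub, "mean_rate", "condition")
    posthoc[[z]] <- posthoc_pairwise(sub, "mean_rate", "condition",
                                     correction = correction)
  }
  inhib <- zone_tab[zone_tab$zone %in%
                      c("pre_cue_inhibition", "post_cue_inhibition"), ]
  cue_inhibition <- rm_anova(inhib, "mean_rate", c("zone", "condition"))
  rt_test <- NULL
  if (!is.null(rt_tab)) {
    wide <- tidyr::pivot_wider(rt_tab, names_from = "condition",
                               values_from = "reaction_time")
    rt_test <- paired_t(wide$reach_invisible, wide$reach_visible)
  }
  list(zone_by_condition = zone_by_condition, one_way = one_way,
       posthoc = posthoc, cue_inhibition = cue_inhibition,
       rt_test = rt_test)
}
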