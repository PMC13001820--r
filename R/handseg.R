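#' Segment a hand movement with percent-of-peak criteria
#'
#' Finds the reach onset and offset from the hand speed and acceleration:
#' the onset is the last time before the speed peak at which speed crosses
#' up through 5% of peak speed while the hand is accelerating at no less
#' than 5% of its (pre-peak) peak acceleration; the offset is the first
#' time after the peak at which speed falls below 5% of peak speed while
#' the hand is decelerating at no less than 5% of its (post-peak) peak
#' deceleration magnitude.
#'
#' @param speed Tibble `time`, `speed` (cm/s), or a velocity tibble
#'   `time`, `x`, `y` from which the 2D speed is computed.
#' @param accel Tibble `time`, `accel` (cm/s^2, signed rate of change of
#'   speed) or `NULL` to differentiate `speed` internally.
#' @param t_from Restrict the search to `time >= t_from` (e.g. the go cue).
#' @param criterion Fraction of the peaks used by both rules (default 0.05).
#' @return A list `t_onset`, `t_offset`, `duration`, `peak_velocity`,
#'   `t_peak`.
#' @export
find_movement_onset_offset <- function(speed, accel = NULL, t_from = -Inf,
                                       criterion = 0.05) {
  if (!"speed" %in% names(speed)) {
    speed <- tibble::tibble(time = speed$time,
                            speed = sqrt(speed$x^2 + speed$y^2))
  }
  keep <- speed$time >= t_from & !is.na(speed$speed)
  tt <- speed$time[keep]
  sp <- speed$speed[keep]
  if (length(sp) < 5) stop("Too few samples to segment.", call. = FALSE)
  if (is.null(accel)) {
    dt <- tt[2] - tt[1]
    n <- length(sp)
    ac <- rep(NA_real_, n)
    ac[2:(n - 1)] <- (sp[3:n] - sp[1:(n - 2)]) / (2 * dt)
    ac[1] <- ac[2]
    ac[n] <- ac[n - 1]
  } else {
    ac <- accel$accel[keep]
  }
  i_peak <- which.max(sp)
  v_peak <- sp[i_peak]
  if (!is.finite(v_peak) || v_peak <= 0) {
    stop("No positive speed peak found.", call. = FALSE)
  }
  v_thr <- criterion * v_peak
  a_peak_pre <- max(ac[seq_len(i_peak)], na.rm = TRUE)
  a_peak_post <- max(-ac[i_peak:length(ac)], na.rm = TRUE)
  if (a_peak_pre <= 0 || a_peak_post <= 0) {
    stop("Hand does not accelerate/decelerate; cannot segment.",
         call. = FALSE)
  }

  # onset: last upward crossing of v_thr before the peak, accelerating
  pre <- seq_len(i_peak)
  up <- which(sp[pre] >= v_thr & dplyr::lag(sp[pre]) < v_thr &
                ac[pre] >= criterion * a_peak_pre)
  if (length(up) == 0) {
    stop("No movement onset found: speed never crosses ",
         signif(v_thr, 3), " cm/s under the acceleration criterion.",
         call. = FALSE)
  }
  i_on <- max(up)

  # offset: first downward crossing of v_thr after the peak, decelerating
  post <- i_peak:length(sp)
  dn <- which(sp[post] <= v_thr & dplyr::lag(sp[post]) > v_thr &
                -ac[post] >= criterion * a_peak_post)
  if (length(dn) == 0) {
    stop("No movement offset found after the speed peak.", call. = FALSE)
  }
  i_off <- post[min(dn)]

  list(t_onset = tt[i_on], t_offset = tt[i_off],
       duration = tt[i_off] - tt[i_on], peak_velocity = v_peak,
       t_peak = tt[i_peak])
}

#' Mid-range average hand speed
#'
#' Mean 2D hand speed over the interval between the first crossings of 25%
#' and 75% of the vertical distance from start to target; this is the
#' speed-feedback metric shown to participants after each trial (goal
#' 20 cm/s).
#'
#' @param trace Hand position tibble `time`, `x`, `y` (cm).
#' @param y_start,y_target Start and target y coordinates, cm (defaults
#'   from [geometry_config()]).
#' @return Average speed in cm/s.
#' @export
mid_range_avg_speed <- function(trace, y_start = 0, y_target = 20) {
  y25 <- y_start + 0.25 * (y_target - y_start)
  y75 <- y_start + 0.75 * (y_target - y_start)
  dirn <- sign(y_target - y_start)
  i25 <- which(dirn * trace$y >= dirn * y25)[1]
  i75 <- which(dirn * trace$y >= dirn * y75)[1]
  if (is.na(i25) || is.na(i75) || i75 <= i25) {
    stop("Hand never crosses the 25%/75% y-distance marks.", call. = FALSE)
  }
  vel <- differentiate(trace[i25:i75, ], order = 1)
  mean(sqrt(vel$x^2 + vel$y^2), na.rm = TRUE)
}

# End of the first run of at least `run_s` seconds for which `flag` holds,
# searching from `t_from`. Returns NA if no such run completes.
first_sustained_run_end <- function(time, flag, run_s, t_from = -Inf) {
  sel <- time >= t_from
  time <- time[sel]
  flag <- flag[sel]
  flag[is.na(flag)] <- FALSE
  rate <- round(1 / (time[2] - time[1]))
  need <- round(run_s * rate)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0) return(NA_real_)
  time[starts[ok[1]]] + run_s
}

#' Trial end for the visible-cursor reach
#'
#' The trial ends once the cursor has been inside the target disc for
#' 500 ms; re-entries restart the run.
#'
#' @param cursor Cursor position tibble `time`, `x`, `y` (cm) at 1000 Hz.
#' @param target_position Target centre `c(x, y)` in cm.
#' @param target_radius Target radius, cm (default 1).
#' @param t_from Search start, s.
#' @return Trial-end time, s.
#' @export
trial_end_reach_visible <- function(cursor,
                                    target_position = c(0, 20),
                                    target_radius = 1, t_from = -Inf) {
  inside <- sqrt((cursor$x - target_position[1])^2 +
                   (cursor$y - target_position[2])^2) <= target_radius
  t_end <- first_sustained_run_end(cursor$time, inside, 0.5, t_from)
  if (is.na(t_end)) {
    stop("Cursor never dwelt inside the target for 500 ms.", call. = FALSE)
  }
  t_end
}

#' Trial end for the invisible-cursor reach
#'
#' The trial ends once the hand speed has stayed below 10 cm/s for 200 ms.
#' The rule only makes sense once the reach is under way, so the run is
#' searched from the post-onset speed peak (the rising flank of a slow
#' reach is itself below threshold and must not end the trial).
#'
#' @param speed Tibble `time`, `speed` (cm/s) or velocity tibble
#'   `time`, `x`, `y`.
#' @param t_onset Movement onset, s.
#' @param threshold Speed threshold, cm/s (default 10).
#' @return Trial-end time, s.
#' @export
trial_end_reach_invisible <- function(speed, t_onset, threshold = 10) {
  if (is.null(t_onset) || is.na(t_onset)) {
    stop("No movement onset: the stillness rule applies only after the ",
         "hand has moved.", call. = FALSE)
  }
  if (!"speed" %in% names(speed)) {
    speed <- tibble::tibble(time = speed$time,
                            speed = sqrt(speed$x^2 + speed$y^2))
  }
  post <- speed$time >= t_onset
  t_peak <- speed$time[post][which.max(speed$speed[post])]
  t_end <- first_sustained_run_end(speed$time, speed$speed < threshold,
                                   0.2, t_from = t_peak)
  if (is.na(t_end)) {
    stop("Hand speed never stayed below ", threshold, " cm/s for 200 ms.",
         call. = FALSE)
  }
  t_end
}

#' Segment one trial's hand data
#'
#' Convenience wrapper: filters the hand series (10-Hz zero-phase
#' Butterworth), differentiates, segments the post-go movement and returns
#' a one-row tibble of kinematic summaries including the reaction time
#' relative to the go cue and the mid-range average speed.
#'
#' @param hand Raw hand tibble `time`, `x`, `y` at 1000 Hz.
#' @param t_go Go-cue time, s.
#' @return One-row tibble: `t_onset`, `t_offset`, `duration`,
#'   `reaction_time`, `peak_velocity`, `mid_range_speed`.
#' @export
segment_hand <- function(hand, t_go) {
  filt <- filter_hand(hand)
  vel <- differentiate(filt, order = 1)
  seg <- find_movement_onset_offset(vel, t_from = t_go)
  mrs <- tryCatch(mid_range_avg_speed(filt), error = function(e) NA_real_)
  tibble::tibble(
    t_onset = seg$t_onset, t_offset = seg$t_offset,
    duration = seg$duration, reaction_time = seg$t_onset - t_go,
    peak_velocity = seg$peak_velocity, mid_range_speed = mrs
  )
}
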