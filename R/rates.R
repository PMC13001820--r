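#' Named analysis zones relative to the go cue
#'
#' Fixed time windows (seconds relative to the go cue) over which
#' microsaccade rates are averaged: the initial-fixation zone
#' (-1.75 to -1.65 s), three pre-cue zones of 250/375/500 ms ending at the
#' cue, the post-inhibition zone (+0.3 to +0.8 s), and the narrow pre- and
#' post-cue inhibition zones (-0.1 to 0 and +0.15 to +0.25 s) used to probe
#' the sharp inhibition right after the cue. The movement zone has no fixed
#' window; it is normalised per trial (see [movement_zone_rate()]).
#'
#' @return A tibble `zone`, `t_start`, `t_end`.
#' @export
zone_definitions <- function() {
  tibble::tribble(
    ~zone,               ~t_start, ~t_end,
    "initial_fixation",  -1.75,    -1.65,
    "pre_cue_250",       -0.25,     0,
    "pre_cue_375",       -0.375,    0,
    "pre_cue_500",       -0.5,      0,
    "post_inhibition",    0.3,      0.8,
    "pre_cue_inhibition", -0.1,     0,
    "post_cue_inhibition", 0.15,    0.25
  )
}

# Common scaffolding: per-trial event tables aligned to the go cue.
# `trials` needs columns t_go, t_window_start, t_window_end and a list
# column `events` of tibbles with t_onset/t_offset (absolute trial time).
align_trials <- function(trials, t_min, t_max, dt = 0.001) {
  t <- seq(t_min, t_max, by = dt)
  list(t = t, dt = dt)
}

#' Microsaccade rate from the binary state method
#'
#' For each trial a binary state is 1 while a microsaccade is in flight and
#' 0 otherwise. Trials are aligned to the go cue; at each millisecond the
#' states are averaged across the trials whose analysis window covers that
#' time, giving the proportion of trials with an ongoing microsaccade,
#' which is converted to a rate in Hz by dividing by the average
#' microsaccade duration.
#'
#' @param trials Tibble with `t_go`, `t_window_start`, `t_window_end`
#'   (absolute trial times delimiting each trial's contribution; typically
#'   target appearance and trial end) and a list-column `events`
#'   (tibbles with `t_onset`, `t_offset`).
#' @param mean_event_duration Average microsaccade duration in seconds;
#'   `NULL` uses the mean duration of all events in `trials`.
#' @param t_min,t_max Support of the returned series, s relative to the go
#'   cue (defaults -1.8 to +0.8).
#' @return A `rate_series` tibble: `t` (s relative to the cue), `rate`
#'   (Hz), `n_trials` (contributing trials at each t), with the method in
#'   attribute `method`.
#' @export
rate_state_method <- function(trials, mean_event_duration = NULL,
                              t_min = -1.8, t_max = 0.8) {
  stopifnot(nrow(trials) >= 1)
  if (is.null(mean_event_duration)) {
    durs <- unlist(lapply(trials$events, function(e) {
      if (nrow(e)) e$t_offset - e$t_onset else numeric()
    }))
    if (length(durs) == 0) {
      stop("No events in `trials`; supply `mean_event_duration`.",
           call. = FALSE)
    }
    mean_event_duration <- mean(durs)
  }
  if (mean_event_duration <= 0) {
    stop("`mean_event_duration` must be positive.", call. = FALSE)
  }
  dt <- 0.001
  t <- seq(t_min, t_max, by = dt)
  state_sum <- numeric(length(t))
  n_cover <- numeric(length(t))
  for (i in seq_len(nrow(trials))) {
    rel_lo <- trials$t_window_start[i] - trials$t_go[i]
    rel_hi <- trials$t_window_end[i] - trials$t_go[i]
    cover <- t >= rel_lo & t <= rel_hi
    n_cover <- n_cover + cover
    ev <- trials$events[[i]]
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        on <- ev$t_onset[k] - trials$t_go[i]
        off <- ev$t_offset[k] - trials$t_go[i]
        state_sum <- state_sum + (cover & t >= on & t <= off)
      }
    }
  }
  rate <- ifelse(n_cover > 0, state_sum / pmax(n_cover, 1) /
                   mean_event_duration, 0)
  out <- tibble::tibble(t = t, rate = rate, n_trials = n_cover)
  attr(out, "method") <- "state_based"
  class(out) <- c("rate_series", class(out))
  out
}

#' Microsaccade rate from the causal-kernel method
#'
#' Counts microsaccade onsets per millisecond across trials (aligned to
#' the go cue), convolves the counts with the causal kernel
#' `w(tau) = alpha^2 * tau * exp(-alpha * tau)` for `tau >= 0` (unit
#' integral, peak at `tau = 1/alpha`), and divides by the number of trials
#' covering each time point, yielding a smooth rate in Hz.
#'
#' @inheritParams rate_state_method
#' @param alpha Kernel rate parameter in 1/s (default `1/0.05`, i.e. a
#'   50-ms kernel time constant).
#' @return A `rate_series` tibble (see [rate_state_method()]).
#' @export
rate_kernel_method <- function(trials, alpha = 1 / 0.05,
                               t_min = -1.8, t_max = 0.8) {
  stopifnot(nrow(trials) >= 1)
  if (alpha <= 0) stop("`alpha` must be positive.", call. = FALSE)
  dt <- 0.001
  # extend the grid one kernel length back so onsets before t_min still
  # contribute their mass inside the window
  k_len <- ceiling(12 / alpha / dt)
  t <- seq(t_min - k_len * dt, t_max, by = dt)
  counts <- numeric(length(t))
  n_cover <- numeric(length(t))
  for (i in seq_len(nrow(trials))) {
    rel_lo <- trials$t_window_start[i] - trials$t_go[i]
    rel_hi <- trials$t_window_end[i] - trials$t_go[i]
    n_cover <- n_cover + (t >= rel_lo & t <= rel_hi)
    ev <- trials$events[[i]]
    if (nrow(ev)) {
      idx <- round((ev$t_onset - trials$t_go[i] - t[1]) / dt) + 1
      idx <- idx[idx >= 1 & idx <= length(t)]
      for (j in idx) counts[j] <- counts[j] + 1
    }
  }
  tau <- (0:k_len) * dt
  w <- alpha^2 * tau * exp(-alpha * tau) * dt  # discrete unit-mass kernel
  # causal FIR: sm[i] = sum_j w[j] * counts[i - j]
  sm <- as.numeric(stats::filter(counts, w, method = "convolution",
                                 sides = 1))
  sm[is.na(sm)] <- 0
  rate <- ifelse(n_cover > 0, sm / pmax(n_cover, 1) / dt, 0)
  keep <- t >= t_min
  out <- tibble::tibble(t = t[keep], rate = rate[keep],
                        n_trials = n_cover[keep])
  attr(out, "method") <- "causal_kernel"
  class(out) <- c("rate_series", class(out))
  out
}

#' Average rate over a named zone
#'
#' @param series A `rate_series` tibble from [rate_state_method()] or
#'   [rate_kernel_method()].
#' @param zone Zone name (see [zone_definitions()]) or a numeric
#'   `c(t_start, t_end)` in seconds relative to the go cue.
#' @return Mean rate in Hz over the zone's samples.
#' @export
zone_average <- function(series, zone) {
  if (is.character(zone)) {
    zd <- zone_definitions()
    row <- zd[zd$zone == zone, ]
    if (nrow(row) != 1) stop("Unknown zone `", zone, "`.", call. = FALSE)
    zone <- c(row$t_start, row$t_end)
  }
  if (zone[1] < min(series$t) - 1e-9 || zone[2] > max(series$t) + 1e-9) {
    stop("Zone window lies outside the rate-series support.", call. = FALSE)
  }
  sel <- series$t >= zone[1] - 1e-9 & series$t <= zone[2] + 1e-9
  mean(series$rate[sel])
}

#' Movement-zone microsaccade rate
#'
#' The movement zone is normalised per trial: microsaccade onsets are
#' counted inside each trial's movement phase (kinematic onset to offset
#' for reaches; the scheduled interval for the passive conditions), the
#' counts and phase durations are summed across trials, and the totals are
#' divided, giving one rate in Hz per participant-condition cell.
#'
#' @param trials Tibble with list-column `events` and columns
#'   `t_move_start`, `t_move_end` (absolute trial time).
#' @return Rate in Hz.
#' @export
movement_zone_rate <- function(trials) {
  durations <- trials$t_move_end - trials$t_move_start
  total_dur <- sum(durations)
  if (!isTRUE(total_dur > 0)) {
    stop("Total movement duration must be positive.", call. = FALSE)
  }
  n_onsets <- sum(vapply(seq_len(nrow(trials)), function(i) {
    ev <- trials$events[[i]]
    if (!nrow(ev)) return(0L)
    sum(ev$t_onset >= trials$t_move_start[i] &
          ev$t_onset <= trials$t_move_end[i])
  }, integer(1)))
  n_onsets / total_dur
}
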