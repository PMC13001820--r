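# Independent oracles used across the suite. These are deliberately naive
# implementations (per-sample loops, closed forms, root finding) kept
# separate from the package's own code paths.

# Brute-force microsaccade scan: walk the velocity samples one by one,
# apply the elliptic criterion, track runs manually, and keep runs of at
# least `min_n` samples. Returns onset/offset sample indices.
oracle_detect <- function(vx, vy, eta_x, eta_y, min_n = 40) {
  n <- length(vx)
  onsets <- integer()
  offsets <- integer()
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    outside <- !is.na(vx[i]) && !is.na(vy[i]) &&
      (vx[i] / eta_x)^2 + (vy[i] / eta_y)^2 > 1
    if (outside && is.na(run_start)) run_start <- i
    if (!outside && !is.na(run_start)) {
      if (i - run_start >= min_n) {
        onsets <- c(onsets, run_start)
        offsets <- c(offsets, i - 1L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && n - run_start + 1 >= min_n) {
    onsets <- c(onsets, run_start)
    offsets <- c(offsets, n)
  }
  list(onsets = onsets, offsets = offsets)
}

# Closed-form magnitude response of a zero-phase (two-pass) Butterworth
# low-pass of order n with cutoff fc.
oracle_butter_gain <- function(f, fc, n) {
  1 / (1 + (f / fc)^(2 * n))  # |H|^2 per pass = |H| after two passes
}

# Root-finding oracle for the minimum-jerk onset criterion: the normalised
# time tau at which the speed profile 30 tau^2 (1-tau)^2 crosses
# `frac` of its peak 1.875.
oracle_onset_fraction <- function(frac = 0.05) {
  stats::uniroot(function(u) 30 * u^2 * (1 - u)^2 - frac * 1.875,
                 c(1e-6, 0.5), tol = 1e-12)$root
}

# Root-finding oracle for normalised times at which the minimum-jerk
# displacement reaches a fraction `p` of the amplitude.
oracle_mj_fraction_time <- function(p) {
  stats::uniroot(function(u) 10 * u^3 - 15 * u^4 + 6 * u^5 - p,
                 c(0, 1), tol = 1e-12)$root
}

# Smooth unit step (minimum-jerk shape) for building synthetic gaze steps
# inside tests.
mj_step_for_tests <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

# A minimal noiseless minimum-jerk reach trace at 1000 Hz.
make_clean_reach <- function(rt = 0.4, d = 1.36, a = 20, t_go = 1.9,
                             t_from = 0, t_to = t_go + rt + d + 1) {
  t <- seq(t_from, t_to, by = 0.001)
  u <- pmin(pmax((t - t_go - rt) / d, 0), 1)
  y <- a * (10 * u^3 - 15 * u^4 + 6 * u^5)
  tibble::tibble(time = t, x = 0, y = y)
}

# Trials table for the rate estimators: `events` drawn directly at known
# onset times (go cue at time 0).
make_rate_trials <- function(events_list, window = c(-1.9, 0.9)) {
  tibble::tibble(
    t_go = 0,
    t_window_start = window[1],
    t_window_end = window[2],
    events = events_list
  )
}
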