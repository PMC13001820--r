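no_events <- function() {
  tibble::tibble(t_onset = numeric(), t_offset = numeric())
}

test_that("state-based rate equals occupancy over mean duration", {
  # 10 trials all in-event at t* = 0.2 with mean duration 0.08 -> 12.5 Hz
  ev <- tibble::tibble(t_onset = 0.15, t_offset = 0.23)
  trials <- make_rate_trials(rep(list(ev), 10))
  rs <- rate_state_method(trials, mean_event_duration = 0.080)
  expect_equal(rs$rate[which.min(abs(rs$t - 0.2))], 12.5)
  expect_true(all(rs$rate >= 0))
  # no events anywhere -> identically zero
  empty <- make_rate_trials(rep(list(no_events()), 5))
  rs0 <- rate_state_method(empty, mean_event_duration = 0.08)
  expect_true(all(rs0$rate == 0))
  expect_error(rate_state_method(trials, mean_event_duration = 0),
               "positive")
  # only covering trials contribute: n_trials reflects each window
  short <- make_rate_trials(list(ev, no_events()),
                            window = c(-0.5, 0.5))
  short$t_window_start[2] <- 0.4
  rs2 <- rate_state_method(short, mean_event_duration = 0.08,
                           t_min = -0.5, t_max = 0.5)
  expect_equal(rs2$n_trials[which.min(abs(rs2$t + 0.2))], 1)
  expect_equal(rs2$n_trials[which.min(abs(rs2$t - 0.45))], 2)
})

test_that("the causal kernel has unit mass and peaks 1/alpha after an onset", {
  alpha <- 1 / 0.05
  one <- make_rate_trials(list(tibble::tibble(t_onset = -0.5,
                                              t_offset = -0.44)))
  rs <- rate_kernel_method(one, alpha = alpha)
  dt <- rs$t[2] - rs$t[1]
  expect_equal(sum(rs$rate) * dt, 1, tolerance = 1e-3)
  expect_equal(rs$t[which.max(rs$rate)], -0.5 + 1 / alpha,
               tolerance = 0.002)
  zero <- make_rate_trials(rep(list(no_events()), 3))
  expect_true(all(rate_kernel_method(zero)$rate == 0))
  expect_error(rate_kernel_method(one, alpha = 0), "positive")
})

test_that("zone averages follow hand-computed values", {
  t <- seq(-1.8, 0.8, by = 0.001)
  const <- structure(tibble::tibble(t = t, rate = 2, n_trials = 1),
                     class = c("rate_series", "tbl_df", "tbl", "data.frame"))
  for (z in zone_definitions()$zone) {
    expect_equal(zone_average(const, z), 2)
  }
  ramp_rate <- ifelse(t >= -1 & t <= 0, t + 1, 0)
  ramp <- structure(tibble::tibble(t = t, rate = ramp_rate, n_trials = 1),
                    class = class(const))
  expect_equal(zone_average(ramp, c(-0.5, 0)), 0.75, tolerance = 1e-3)
  empty <- structure(tibble::tibble(t = t, rate = 0, n_trials = 0),
                     class = class(const))
  expect_equal(zone_average(empty, "pre_cue_250"), 0)
  expect_error(zone_average(const, c(-3, 0)), "support")
  expect_error(zone_average(const, "no_such_zone"), "Unknown")
})

test_that("movement-zone rate pools onsets and durations across trials", {
  ev1 <- tibble::tibble(t_onset = 0.5, t_offset = 0.56)
  ev3 <- tibble::tibble(t_onset = c(0.4, 0.8, 1.2),
                        t_offset = c(0.46, 0.86, 1.26))
  trials <- tibble::tibble(
    t_move_start = c(0, 0, 0),
    t_move_end = c(1, 1, 2),
    events = list(ev1, no_events(), ev3)
  )
  expect_equal(movement_zone_rate(trials), 4 / 4)  # 4 onsets / 4 s
  trials2 <- dplyr::mutate(trials, t_move_end = t_move_start +
                             2 * (t_move_end - t_move_start))
  expect_equal(movement_zone_rate(trials2), 0.5)
  none <- dplyr::mutate(trials, events = list(no_events(), no_events(),
                                              no_events()))
  expect_equal(movement_zone_rate(none), 0)
  bad <- dplyr::mutate(trials, t_move_end = t_move_start)
  expect_error(movement_zone_rate(bad), "positive")
})

test_that("state and kernel estimates agree on stationary data", {
  # 400 trials at a constant 1.2 Hz; the two estimators' time averages
  # agree within 10% relative and sit near the true rate
  set.seed(61)
  lam <- 1.2
  trials <- make_rate_trials(lapply(1:400, function(i) {
    n <- stats::rpois(1, lam * 2.8)
    on <- sort(stats::runif(n, -1.9, 0.9))
    tibble::tibble(t_onset = on, t_offset = on + 0.08)
  }))
  st <- rate_state_method(trials)
  kn <- rate_kernel_method(trials)
  m_st <- mean(st$rate)
  m_kn <- mean(kn$rate)
  expect_lt(abs(m_st - m_kn) / m_st, 0.10)
  se <- sqrt(lam / (400 * 2.6))
  expect_lt(abs(m_st - lam), 3 * se + 0.05)
})

test_that("both estimators recover a planted inhibition profile's ordering", {
  set.seed(71)
  prof <- rate_piecewise_task()
  ok_state <- 0
  ok_kernel <- 0
  zones <- c("initial_fixation", "post_inhibition", "pre_cue_250",
             "post_cue_inhibition")
  for (rep in 1:20) {
    trials <- make_rate_trials(lapply(1:200, function(i) {
      delay <- stats::runif(1, 1.8, 2.0)
      ev <- reachsacc:::draw_microsaccades(
        -delay, 1.0, prof$rate_fn,
        amp_mean = 0.95, amp_sd = 0.25, amp_range = c(0.3, 1.8),
        dur_mean = 0.086, dur_sd = 0.015, dur_range = c(0.05, 0.13))
      ev[c("t_onset", "t_offset")]
    }))
    vs <- vapply(zones, function(z)
      zone_average(rate_state_method(trials), z), numeric(1))
    vk <- vapply(zones, function(z)
      zone_average(rate_kernel_method(trials), z), numeric(1))
    ok_state <- ok_state + all(diff(vs) < 0)
    ok_kernel <- ok_kernel + all(diff(vk) < 0)
  }
  expect_gte(ok_state, 19)
  expect_gte(ok_kernel, 19)
})
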