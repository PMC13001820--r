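sched_3s <- function(delay = 1.9, t_end = 3.09) {
  s <- event_schedule("cue_monitoring", delay_duration = delay)
  s$t_trial_end <- t_end
  s
}

test_that("zero-rate profiles inject no events and negative rates error", {
  g <- simulate_fixational_gaze(sched_3s(), rate_constant(0), seed = 1)
  expect_equal(nrow(g$events), 0)
  expect_error(rate_constant(-1), "non-negative")
  expect_error(rate_linear_ramp(-0.5, 1, 0, 1), "non-negative")
})

test_that("injected event counts match the rate integral (Poisson band)", {
  # 200 trials x 3 s of fixation at a constant 1 Hz: expect 600 +- 3*sqrt(600)
  set.seed(42)
  sched <- sched_3s()
  total <- 0
  for (i in 1:200) {
    g <- simulate_fixational_gaze(sched, rate_constant(1.0), seed = NULL)
    ev <- g$events
    expect_true(all(ev$t_onset >= 0 & ev$t_offset <= sched$t_trial_end))
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$t_onset) > 0))
      expect_true(all(ev$t_onset[-1] >= ev$t_offset[-nrow(ev)]))
    }
    total <- total + nrow(ev)
  }
  expect_gt(total, 600 - 3 * sqrt(600))
  expect_lt(total, 600 + 3 * sqrt(600))
})

test_that("gaze stays near the target and events follow a main sequence", {
  g <- simulate_fixational_gaze(sched_3s(), rate_constant(2), seed = 5)
  gz <- g$gaze[g$gaze$time >= g$fixation$t_fix_start, ]
  dist <- sqrt(gz$x^2 + (gz$y - 20)^2)
  expect_true(all(dist < 6, na.rm = TRUE))
  ev <- g$events
  expect_gt(nrow(ev), 2)
  expect_equal(ev$peak_velocity, 1.875 * ev$amplitude / ev$duration)
  # peak velocity increases with amplitude at fixed duration by construction
  expect_true(all(ev$peak_velocity > 0))
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- simulate_fixational_gaze(sched_3s(), rate_constant(1), seed = 7)
  b <- simulate_fixational_gaze(sched_3s(), rate_constant(1), seed = 7)
  expect_identical(a, b)
  ha <- simulate_hand_reach(sched_3s(), rt = 0.4, seed = 3)
  hb <- simulate_hand_reach(sched_3s(), rt = 0.4, seed = 3)
  expect_identical(ha, hb)
  da <- generate_dataset(n_participants = 1, n_trials_per_condition = 2,
                         seed = 9)
  db <- generate_dataset(n_participants = 1, n_trials_per_condition = 2,
                         seed = 9)
  expect_identical(da, db)
})

test_that("noiseless hand reaches hit the amplitude and peak-speed closed forms", {
  sched <- event_schedule("reach_visible", delay_duration = 1.9)
  sched$t_trial_end <- NA_real_
  h <- simulate_hand_reach(sched, rt = 0.4, d = 1.36, a = 20,
                           noise_sd = 0, seed = 1)
  off <- h$truth$t_offset
  expect_equal(off, 1.9 + 0.4 + 1.36)
  y_at_off <- h$hand$y[which.min(abs(h$hand$time - off))]
  expect_equal(y_at_off, 20, tolerance = 1e-9)
  vel <- differentiate(h$hand, order = 1)
  expect_equal(max(sqrt(vel$x^2 + vel$y^2), na.rm = TRUE), 1.875 * 20 / 1.36,
               tolerance = 1e-4)
  expect_equal(h$truth$peak_velocity, 1.875 * 20 / 1.36)
})

test_that("generate_dataset produces the study layout with per-condition endings", {
  ds <- generate_dataset(n_participants = 2, n_trials_per_condition = 3,
                         seed = 2)
  expect_equal(nrow(ds), 2 * 4 * 3)
  counts <- dplyr::count(ds, participant, condition)
  expect_true(all(counts$n == 3))
  expect_true(all(ds$t_go - ds$t_show_target >= 1.8 &
                    ds$t_go - ds$t_show_target <= 2.0))
  cm <- ds[ds$condition == "cue_monitoring", ]
  expect_equal(cm$t_trial_end, cm$t_go + 0.3 + 0.8)
  ct <- ds[ds$condition == "cursor_tracking", ]
  expect_equal(ct$t_trial_end, ct$t_go + 0.3 + ct$cursor_move_duration)
  expect_true(all(ct$cursor_move_duration >= 1.15 &
                    ct$cursor_move_duration <= 1.35))
  rv <- ds[ds$condition == "reach_visible", ]
  expect_true(all(rv$t_trial_end > rv$t_go + rv$rt_true))
  expect_true(all(vapply(ds$gaze, nrow, integer(1)) > 0))
  # invisible reaches carry no cursor stream
  ri <- ds[ds$condition == "reach_invisible", ]
  expect_true(all(vapply(ri$cursor, is.null, logical(1))))
  expect_equal(unique(ds$violation), "none")
})

test_that("trial files round-trip through the delimited format", {
  ds <- generate_dataset(n_participants = 1, n_trials_per_condition = 1,
                         seed = 4)
  dir <- withr::local_tempdir()
  write_trials(ds, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 4)
  back <- read_trials(dir)
  expect_equal(nrow(back), nrow(ds))
  back <- back[order(back$condition), ]
  ds2 <- ds[order(ds$condition), ]
  for (i in seq_len(nrow(ds2))) {
    expect_equal(back$gaze[[i]], ds2$gaze[[i]], tolerance = 1e-9)
    expect_equal(back$hand[[i]], ds2$hand[[i]], tolerance = 1e-9)
    expect_equal(back$events_true[[i]]$t_onset,
                 ds2$events_true[[i]]$t_onset, tolerance = 1e-9)
    expect_equal(back$t_go[i], ds2$t_go[i])
    expect_equal(back$violation[i], ds2$violation[i])
  }
})
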