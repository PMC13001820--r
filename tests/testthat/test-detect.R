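vel_tbl <- function(vx, vy = rep(0, length(vx)), rate = 1000) {
  tibble::tibble(time = (seq_along(vx) - 1) / rate, x = vx, y = vy)
}

test_that("median-based SD thresholds match hand arithmetic and scale", {
  vel <- vel_tbl(c(-2, -2, 0, 2, 2), c(-1, -1, 0, 1, 1))
  th <- compute_thresholds(vel, lambda = 5)
  expect_equal(th$sigma_x, 2)   # median(v^2)=4, median(v)=0
  expect_equal(th$eta_x, 10)
  expect_equal(th$sigma_y, 1)
  expect_equal(th$eta_y, 5)
  th3 <- compute_thresholds(dplyr::mutate(vel, x = 3 * x, y = 3 * y))
  expect_equal(th3$eta_x, 3 * th$eta_x)
  expect_equal(th3$eta_y, 3 * th$eta_y)
  expect_error(compute_thresholds(vel_tbl(rep(1, 10), rnorm(10))),
               "x axis")
  expect_error(compute_thresholds(vel[1:4, ]), "at least 5")
})

test_that("ellipse criterion is strict and quiet traces yield no events", {
  th <- structure(list(eta_x = 1, eta_y = 1, sigma_x = 0.2, sigma_y = 0.2,
                       lambda = 5), class = "velocity_thresholds")
  zero <- vel_tbl(rep(0, 500))
  expect_equal(nrow(detect_microsaccades(zero, th)), 0)
  # 100 samples exactly on the boundary: strict inequality, no event
  on_boundary <- vel_tbl(c(rep(0, 100), rep(1, 100), rep(0, 100)))
  expect_equal(nrow(detect_microsaccades(on_boundary, th)), 0)
  just_out <- vel_tbl(c(rep(0, 100), rep(1 + 1e-9, 100), rep(0, 100)))
  expect_equal(nrow(detect_microsaccades(just_out, th)), 1)
  # runs shorter than 40 samples are rejected
  short <- vel_tbl(c(rep(0, 100), rep(2, 39), rep(0, 100)))
  expect_equal(nrow(detect_microsaccades(short, th)), 0)
  expect_warning(detect_microsaccades(zero[1:20, ], th), "shorter")
})

test_that("detector equals the brute-force oracle on random traces", {
  set.seed(1234)
  for (rep in 1:25) {
    n <- sample(500:5000, 1)
    vx <- stats::rnorm(n, 0, 0.3)
    vy <- stats::rnorm(n, 0, 0.3)
    # inject a few strong bursts of random length (some below 40 samples)
    for (k in seq_len(sample(0:4, 1))) {
      len <- sample(10:120, 1)
      i0 <- sample(1:(n - len), 1)
      ang <- stats::runif(1, 0, 2 * pi)
      mag <- stats::runif(1, 2, 15)
      vx[i0:(i0 + len - 1)] <- vx[i0:(i0 + len - 1)] + mag * cos(ang)
      vy[i0:(i0 + len - 1)] <- vy[i0:(i0 + len - 1)] + mag * sin(ang)
    }
    vel <- vel_tbl(vx, vy)
    th <- compute_thresholds(vel, lambda = 5)
    got <- detect_microsaccades(vel, th)
    want <- oracle_detect(vx, vy, th$eta_x, th$eta_y, min_n = 40)
    expect_equal(nrow(got), length(want$onsets))
    if (nrow(got) > 0) {
      expect_equal(got$t_onset, vel$time[want$onsets])
      expect_equal(got$t_offset, vel$time[want$offsets])
    }
  }
})

test_that("detection is scale invariant and monotone in lambda", {
  set.seed(99)
  n <- 4000
  vx <- stats::rnorm(n, 0, 0.3)
  vy <- stats::rnorm(n, 0, 0.3)
  vx[1000:1080] <- vx[1000:1080] + 8
  vy[2500:2560] <- vy[2500:2560] - 6
  vel <- vel_tbl(vx, vy)
  base <- detect_microsaccades(vel, compute_thresholds(vel))
  for (c_scale in c(0.01, 0.5, 7, 1000)) {
    sv <- dplyr::mutate(vel, x = c_scale * x, y = c_scale * y)
    got <- detect_microsaccades(sv, compute_thresholds(sv))
    expect_equal(got$t_onset, base$t_onset)
    expect_equal(got$t_offset, base$t_offset)
  }
  lambdas <- c(1, 2, 5, 8, 12, 20)
  counts <- vapply(lambdas, function(l) {
    nrow(detect_microsaccades(vel, compute_thresholds(vel, lambda = l)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single injected event is recovered with millisecond onset accuracy", {
  # 60-ms, 0.9-cm displacement on low noise
  sched <- event_schedule("cue_monitoring", delay_duration = 1.9)
  sched$t_trial_end <- 3.0
  set.seed(21)
  hits <- 0
  for (rep in 1:20) {
    g <- simulate_fixational_gaze(sched, rate_constant(0), seed = NULL,
                                  noise_sd = 0.001, drift_step = 5e-4,
                                  fix_latency = -1.1)
    t_on <- 1.5 + stats::runif(1, -0.3, 0.3)
    u <- mj_step_for_tests((g$gaze$time - t_on) / 0.06)
    g$gaze$x <- g$gaze$x + 0.9 * u
    up <- upsample_eye(g$gaze)
    vel <- detection_velocity(up)
    ev <- detect_microsaccades(vel, t_from = 0, t_to = 3.0, pos = up)
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$t_onset - t_on), 0.005)
    expect_equal(ev$amplitude, 0.9, tolerance = 0.1)
    hits <- hits + (nrow(ev) == 1)
  }
  expect_equal(hits, 20)
})

test_that("event characterisation uses the Euclidean onset-offset distance", {
  n <- 200
  pos <- tibble::tibble(time = (0:(n - 1)) / 1000,
                        x = c(rep(0, 100), rep(0.3, 100)),
                        y = c(rep(0, 100), rep(0.4, 100)))
  vel <- differentiate(pos, order = 1)
  got <- characterize_events(pos, vel, t_onset = 0.095, t_offset = 0.105)
  expect_equal(got$amplitude, 0.5)  # 3-4-5 triangle
  expect_equal(got$duration, 0.01)
  horiz <- characterize_events(
    dplyr::mutate(pos, y = 0), vel, 0.095, 0.105)
  expect_equal(horiz$amplitude, 0.3)
})
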