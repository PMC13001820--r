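#' Moving-window velocity estimate for microsaccade detection
#'
#' Five-sample moving-window central difference,
#' `v[i] = (x[i+2] + x[i+1] - x[i-1] - x[i-2]) / (6 * dt)`, the standard
#' estimator for velocity-threshold microsaccade detection: it suppresses
#' sample-to-sample noise while preserving saccadic velocity peaks. The
#' first and last two samples are `NA`.
#'
#' @param series Position tibble `time`, `x`, `y`, uniformly sampled.
#' @return A tibble `time`, `x`, `y` of velocities (cm/s).
#' @export
detection_velocity <- function(series) {
  rate <- series_rate(series)
  n <- nrow(series)
  if (n < 5) stop("Series too short for the 5-sample window.", call. = FALSE)
  dt <- 1 / rate
  v_one <- function(x) {
    out <- rep(NA_real_, n)
    i <- 3:(n - 2)
    out[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    out
  }
  tibble::tibble(time = series$time, x = v_one(series$x),
                 y = v_one(series$y))
}

#' Elliptic velocity thresholds from median-based SDs
#'
#' Computes, separately for the horizontal and vertical velocity
#' components, the robust spread estimate
#' `sigma = sqrt(median(v^2) - median(v)^2)` and the detection threshold
#' `eta = lambda * sigma`. The two thresholds define an elliptic criterion
#' in 2D velocity space: a sample is saccadic when
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`.
#'
#' @param vel Velocity tibble `time`, `x`, `y` (cm/s); `NA` samples are
#'   ignored.
#' @param lambda Threshold multiplier in units of median-based SDs
#'   (default 5, the signal-to-noise optimum for this detector).
#' @return A list of class `velocity_thresholds` with `eta_x`, `eta_y`,
#'   `sigma_x`, `sigma_y`, `lambda`.
#' @examples
#' vel <- tibble::tibble(time = (0:4) / 1000,
#'                       x = c(-2, -2, 0, 2, 2), y = c(-1, -1, 0, 1, 1))
#' compute_thresholds(vel)
#' @export
compute_thresholds <- function(vel, lambda = 5) {
  if (lambda <= 0) stop("`lambda` must be positive.", call. = FALSE)
  sig <- function(v, axis) {
    v <- v[!is.na(v)]
    if (length(v) < 5) {
      stop("Need at least 5 valid velocity samples on the ", axis, " axis.",
           call. = FALSE)
    }
    s2 <- stats::median(v^2) - stats::median(v)^2
    if (s2 <= 0) {
      stop("Degenerate (zero) median-based SD on the ", axis, " axis; ",
           "velocities are effectively constant.", call. = FALSE)
    }
    sqrt(s2)
  }
  sx <- sig(vel$x, "x")
  sy <- sig(vel$y, "y")
  structure(list(eta_x = lambda * sx, eta_y = lambda * sy,
                 sigma_x = sx, sigma_y = sy, lambda = lambda),
            class = "velocity_thresholds")
}

#' Detect microsaccades with the elliptic velocity criterion
#'
#' Flags every velocity sample strictly outside the threshold ellipse,
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`, takes maximal runs of consecutive
#' flagged samples as candidate events, and keeps runs of at least
#' `min_duration`. The event onset is the first sample outside the ellipse
#' and the offset the last. Detection is restricted to `[t_from, t_to]`
#' (by default the whole series); samples with missing velocity never count
#' as saccadic.
#'
#' @param vel Velocity tibble `time`, `x`, `y` (cm/s) at 1000 Hz.
#' @param thresholds A `velocity_thresholds` object, or `NULL` to compute
#'   them from `vel` over the detection window with multiplier `lambda`.
#' @param min_duration Minimum event duration in seconds (default 0.040,
#'   i.e. 40 samples at 1000 Hz).
#' @param lambda Threshold multiplier used when `thresholds` is `NULL`.
#' @param t_from,t_to Detection window, seconds (e.g. target appearance and
#'   trial end).
#' @param pos Optional position tibble (same grid as `vel`); when supplied
#'   the returned events carry amplitude (Euclidean onset-to-offset
#'   displacement) and landing coordinates.
#' @return A tibble of events: `t_onset`, `t_offset`, `duration`,
#'   `peak_velocity`, and (with `pos`) `amplitude`, `x_land`, `y_land`.
#' @export
detect_microsaccades <- function(vel, thresholds = NULL,
                                 min_duration = 0.040, lambda = 5,
                                 t_from = -Inf, t_to = Inf, pos = NULL) {
  rate <- series_rate(vel)
  win <- vel$time >= t_from & vel$time <= t_to
  empty <- tibble::tibble(t_onset = numeric(), t_offset = numeric(),
                          duration = numeric(), peak_velocity = numeric())
  if (!is.null(pos)) {
    empty$amplitude <- numeric()
    empty$x_land <- numeric()
    empty$y_land <- numeric()
  }
  if (sum(win) < round(min_duration * rate)) {
    warning("Detection window shorter than `min_duration`; no events.")
    return(empty)
  }
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(vel[win, ], lambda = lambda)
  }
  vx <- vel$x[win]
  vy <- vel$y[win]
  tt <- vel$time[win]
  r2 <- (vx / thresholds$eta_x)^2 + (vy / thresholds$eta_y)^2
  outside <- !is.na(r2) & r2 > 1
  runs <- rle(outside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  min_n <- round(min_duration * rate)
  keep <- which(runs$values & runs$lengths >= min_n)
  if (length(keep) == 0) return(empty)
  ev <- tibble::tibble(
    t_onset = tt[starts[keep]],
    t_offset = tt[ends[keep]],
    duration = tt[ends[keep]] - tt[starts[keep]],
    peak_velocity = vapply(keep, function(k) {
      i <- starts[k]:ends[k]
      max(sqrt(vx[i]^2 + vy[i]^2))
    }, numeric(1))
  )
  if (!is.null(pos)) {
    chr <- characterize_events(pos, vel, ev$t_onset, ev$t_offset)
    ev$amplitude <- chr$amplitude
    ev$x_land <- chr$x_land
    ev$y_land <- chr$y_land
  }
  ev
}

#' Characterise detected events from position and velocity
#'
#' Amplitude is the Euclidean distance between gaze position at onset and
#' at offset; duration is offset minus onset; peak velocity is the maximum
#' 2D speed within the event. Landing coordinates (gaze at offset) support
#' the saccade-landing exclusion rule.
#'
#' @param pos,vel Position / velocity tibbles on the same uniform grid.
#' @param t_onset,t_offset Event times, vectorised.
#' @return A tibble `amplitude`, `duration`, `peak_velocity`, `x_land`,
#'   `y_land`.
#' @export
characterize_events <- function(pos, vel, t_onset, t_offset) {
  i_on <- vapply(t_onset, function(t) which.min(abs(pos$time - t)),
                 integer(1))
  i_off <- vapply(t_offset, function(t) which.min(abs(pos$time - t)),
                  integer(1))
  amp <- sqrt((pos$x[i_off] - pos$x[i_on])^2 +
                (pos$y[i_off] - pos$y[i_on])^2)
  pk <- mapply(function(a, b) {
    i <- a:b
    max(sqrt(vel$x[i]^2 + vel$y[i]^2), na.rm = TRUE)
  }, i_on, i_off)
  tibble::tibble(amplitude = amp, duration = t_offset - t_onset,
                 peak_velocity = pk,
                 x_land = pos$x[i_off], y_land = pos$y[i_off])
}
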