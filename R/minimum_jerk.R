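#' Minimum-jerk displacement profile
#'
#' Position along a straight point-to-point movement that minimises the
#' integrated squared jerk: `y(t) = a * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t / d`. Velocity and acceleration vanish at both endpoints, the peak
#' speed is `1.875 * a / d` at the temporal midpoint, and the displacement is
#' monotone for `a > 0`.
#'
#' @param t Time since movement onset, seconds. Vectorised; every value must
#'   lie in `[0, d]`.
#' @param d Movement duration, seconds (`> 0`).
#' @param a Movement amplitude, cm.
#' @return Displacement in cm, same length as `t`.
#' @examples
#' minimum_jerk_position(c(0, 0.625, 1.25), d = 1.25, a = 20)
#' @export
minimum_jerk_position <- function(t, d, a) {
  check_mj_domain(t, d)
  tau <- t / d
  a * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Minimum-jerk velocity profile
#'
#' Time derivative of [minimum_jerk_position()]:
#' `v(t) = (a / d) * 30 tau^2 (1 - tau)^2`. Peaks at `t = d/2` with value
#' `1.875 * a / d`.
#'
#' @inheritParams minimum_jerk_position
#' @return Velocity in cm/s.
#' @export
minimum_jerk_velocity <- function(t, d, a) {
  check_mj_domain(t, d)
  tau <- t / d
  (a / d) * 30 * tau^2 * (1 - tau)^2
}

#' Minimum-jerk acceleration profile
#'
#' Second derivative of [minimum_jerk_position()]:
#' `(a / d^2) * (60 tau - 180 tau^2 + 120 tau^3)`.
#'
#' @inheritParams minimum_jerk_position
#' @return Acceleration in cm/s^2.
#' @export
minimum_jerk_acceleration <- function(t, d, a) {
  check_mj_domain(t, d)
  tau <- t / d
  (a / d^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)
}

check_mj_domain <- function(t, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("`d` must be a single positive duration in seconds.", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0) || any(t > d + 1e-12)) {
    stop("`t` must lie within [0, d].", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a curved cursor trajectory toward the target
#'
#' Builds the cursor path used in the cursor-tracking condition: the vertical
#' coordinate follows a minimum-jerk displacement of amplitude `a` over
#' duration `d`, while the horizontal coordinate bows out to one side by a
#' maximum of `bow_max` cm at the movement midpoint before returning to the
#' midline at the target. The bow is a half-sine, `x(t) = s * bow_max *
#' sin(pi * t / d)`: smooth, zero at both endpoints and extremal exactly once,
#' at the midpoint.
#'
#' @param a Movement amplitude in cm (default 20, the start-to-target
#'   distance).
#' @param d Movement duration in seconds; the task draws it uniformly from
#'   1.15--1.35 s, default here 1.25 s.
#' @param bow_direction `"left"` or `"right"`; the sign of the lateral bow.
#' @param dt Sample interval in seconds (default 0.001, i.e. 1000 Hz).
#' @param bow_max Maximum absolute lateral deviation in cm (default 0.25).
#' @return A tibble with columns `time` (s since movement onset), `x`, `y`
#'   (cm).
#' @examples
#' traj <- generate_cursor_trajectory(bow_direction = "right")
#' max(abs(traj$x))
#' @export
generate_cursor_trajectory <- function(a = 20, d = 1.25,
                                       bow_direction = c("right", "left"),
                                       dt = 0.001, bow_max = 0.25) {
  bow_direction <- match.arg(bow_direction)
  if (a <= 0) stop("`a` must be positive.", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  t <- seq(0, d, by = dt)
  if (t[length(t)] < d) t <- c(t, d)
  sgn <- if (bow_direction == "right") 1 else -1
  tibble::tibble(
    time = t,
    x = sgn * bow_max * sin(pi * t / d),
    y = minimum_jerk_position(t, d, a)
  )
}

#' Visual angle subtended at the viewing distance
#'
#' Converts an on-screen extent in cm into visual degrees for a given viewing
#' distance, `2 * atan(size / (2 * distance))`. With the task geometry
#' (37-cm viewing distance) 1 cm corresponds to about 1.5 degrees.
#'
#' @param size_cm Extent on the display, cm.
#' @param distance_cm Viewing distance, cm (default 37).
#' @return Visual angle in degrees.
#' @export
visual_angle_deg <- function(size_cm, distance_cm = 37) {
  2 * atan(size_cm / (2 * distance_cm)) * 180 / pi
}
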