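#' @name preprocessing
#' @title Preprocessing of gaze and hand series
#'
#' @description
#' Position series are plain tibbles with columns `time` (s, uniformly
#' spaced), `x` and `y` (cm); missing samples are `NA`. [upsample_eye()]
#' brings the 500-Hz gaze recording onto the 1000-Hz hand time base by
#' linear interpolation (exact at original instants; missing runs longer
#' than 2 samples are propagated, not interpolated). [filter_hand()] and
#' [filter_eye()] apply zero-phase (forward-backward) low-pass Butterworth
#' filters: third order at 10 Hz for the hand, second order at 15 Hz for
#' gaze, with 1 s of reflective padding so the filter transient never
#' touches the data. [differentiate()] takes central-difference derivatives
#' (one-sided at the ends).
NULL

series_rate <- function(series) {
  dt <- diff(series$time)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6)) {
    stop("Series must be uniformly sampled.", call. = FALSE)
  }
  round(1 / dt[1])
}

#' Upsample a 500-Hz gaze series to 1000 Hz
#'
#' @param series Tibble `time`, `x`, `y` at 500 Hz; `NA` marks missing
#'   samples. Missing runs of at most 2 samples are bridged by linear
#'   interpolation; longer runs stay missing in the output.
#' @return The series on the 1000-Hz grid spanning the same interval.
#' @export
upsample_eye <- function(series) {
  rate <- series_rate(series)
  if (rate != 500) {
    stop("`upsample_eye()` expects a 500-Hz input series.", call. = FALSE)
  }
  t_out <- time_grid(series$time[1], series$time[nrow(series)], 1000)
  up_one <- function(v) {
    v <- bridge_short_gaps(v, max_run = 2)
    valid <- !is.na(v)
    if (sum(valid) < 2) return(rep(NA_real_, length(t_out)))
    out <- stats::approx(series$time[valid], v[valid], xout = t_out,
                         rule = 1)$y
    # re-mask spans whose bracketing original samples are not both valid
    idx <- floor((t_out - series$time[1]) * 500 + 1e-9) + 1
    idx2 <- pmin(idx + 1, length(v))
    on_knot <- abs(t_out - series$time[pmin(idx, length(v))]) < 1e-9
    bad <- ifelse(on_knot, !valid[idx], !(valid[idx] & valid[idx2]))
    out[bad] <- NA_real_
    out
  }
  tibble::tibble(time = t_out, x = up_one(series$x), y = up_one(series$y))
}

bridge_short_gaps <- function(v, max_run = 2) {
  r <- rle(is.na(v))
  if (!any(r$values)) return(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fillable <- which(r$values & r$lengths <= max_run &
                      starts > 1 & ends < length(v))
  for (k in fillable) {
    i0 <- starts[k] - 1
    i1 <- ends[k] + 1
    if (!is.na(v[i0]) && !is.na(v[i1])) {
      v[starts[k]:ends[k]] <- v[i0] +
        (v[i1] - v[i0]) * (seq_len(r$lengths[k])) / (r$lengths[k] + 1)
    }
  }
  v
}

# Zero-phase Butterworth low-pass on one numeric vector: reflective padding
# (up to 1 s), one forward and one backward pass.
butter_zero_phase <- function(v, order, cutoff_hz, rate_hz) {
  n <- length(v)
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(n - 1, rate_hz)  # 1 s of reflective padding
  pre <- 2 * v[1] - v[(pad + 1):2]
  post <- 2 * v[n] - v[(n - 1):(n - pad)]
  z <- c(pre, v, post)
  z <- signal::filter(bf, z)
  z <- rev(signal::filter(bf, rev(z)))
  z[(pad + 1):(pad + n)]
}

filter_series <- function(series, order, cutoff_hz, na_action) {
  rate <- series_rate(series)
  filt_one <- function(v) {
    if (anyNA(v)) {
      if (na_action == "error") {
        stop("Series contains missing samples; handle gaps (e.g. route the ",
             "trial to exclusion) before filtering.", call. = FALSE)
      }
      # filter each contiguous valid span separately
      r <- rle(!is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        span <- starts[k]:ends[k]
        if (length(span) > 3 * (order + 1)) {
          v[span] <- butter_zero_phase(v[span], order, cutoff_hz, rate)
        }
      }
      v
    } else {
      butter_zero_phase(v, order, cutoff_hz, rate)
    }
  }
  dplyr::mutate(series, x = filt_one(.data$x), y = filt_one(.data$y))
}

#' @rdname preprocessing
#' @param series Tibble `time`, `x`, `y`, uniformly sampled.
#' @export
filter_hand <- function(series) {
  filter_series(series, order = 3, cutoff_hz = 10, na_action = "error")
}

#' @rdname preprocessing
#' @export
filter_eye <- function(series) {
  filter_series(series, order = 2, cutoff_hz = 15, na_action = "span")
}

#' Differentiate a position series
#'
#' Central differences in the interior, one-sided differences at the ends;
#' `order = 1` gives velocity (cm/s), `order = 2` acceleration (cm/s^2,
#' second central difference). Samples whose stencil touches a missing
#' value come out `NA`.
#'
#' @param series Tibble `time`, `x`, `y`, uniformly sampled.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return A tibble `time`, `x`, `y` of derivatives.
#' @export
differentiate <- function(series, order = 1) {
  rate <- series_rate(series)
  n <- nrow(series)
  if (n < 3) stop("Series too short to differentiate.", call. = FALSE)
  dt <- 1 / rate
  d_one <- function(v) {
    out <- rep(NA_real_, n)
    if (order == 1) {
      out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
      out[1] <- (v[2] - v[1]) / dt
      out[n] <- (v[n] - v[n - 1]) / dt
    } else if (order == 2) {
      out[2:(n - 1)] <- (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / dt^2
      out[1] <- out[2]
      out[n] <- out[n - 1]
    } else {
      stop("`order` must be 1 or 2.", call. = FALSE)
    }
    out
  }
  tibble::tibble(time = series$time, x = d_one(series$x), y = d_one(series$y))
}
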