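#' Microsaccade-rate profiles for the simulator
#'
#' A rate profile describes the instantaneous microsaccade rate (Hz) as a
#' function of time *relative to the go cue* and drives the inhomogeneous
#' point process from which the simulator draws microsaccade onsets.
#'
#' * `rate_constant(r)` — stationary rate `r` Hz.
#' * `rate_linear_ramp(r0, r1, t0, t1)` — `r0` before `t0`, linear ramp to
#'   `r1` at `t1`, `r1` after.
#' * `rate_piecewise_task()` — the task-like profile: a high baseline during
#'   early target fixation that ramps down toward the go cue, a sharp
#'   post-cue inhibition dip, and a partial rebound during the movement
#'   phase. Defaults: `baseline` 1.3 Hz at 1.8 s before the cue, ramping to
#'   `pre_cue` 0.2 Hz at the cue; a dip to `dip` 0.02 Hz over
#'   0.10--0.28 s after the cue; `rebound` 0.6 Hz from 0.3 s after the cue.
#'
#' @param r,r0,r1 Rates in Hz (must be `>= 0`).
#' @param t0,t1 Ramp start/end, seconds relative to the go cue (`t0 < t1`).
#' @param baseline,pre_cue,dip,rebound Rates in Hz for the task-like profile.
#' @return An object of class `rate_profile`: a list with `name`, `params`
#'   and `rate_fn(t_rel_go)`.
#' @examples
#' p <- rate_piecewise_task()
#' p$rate_fn(c(-1.7, -0.1, 0.2, 0.5))
#' @name rate_profiles
NULL

new_rate_profile <- function(name, params, rate_fn) {
  structure(list(name = name, params = params, rate_fn = rate_fn),
            class = "rate_profile")
}

#' @rdname rate_profiles
#' @export
rate_constant <- function(r) {
  if (r < 0) stop("Rates must be non-negative.", call. = FALSE)
  new_rate_profile("constant", list(r = r), function(t) rep(r, length(t)))
}

#' @rdname rate_profiles
#' @export
rate_linear_ramp <- function(r0, r1, t0, t1) {
  if (r0 < 0 || r1 < 0) stop("Rates must be non-negative.", call. = FALSE)
  if (t1 <= t0) stop("`t1` must exceed `t0`.", call. = FALSE)
  new_rate_profile(
    "linear_ramp", list(r0 = r0, r1 = r1, t0 = t0, t1 = t1),
    function(t) {
      u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
      r0 + (r1 - r0) * u
    }
  )
}

#' @rdname rate_profiles
#' @export
rate_piecewise_task <- function(baseline = 1.3, pre_cue = 0.2, dip = 0.02,
                                rebound = 0.6) {
  rs <- c(baseline, pre_cue, dip, rebound)
  if (any(rs < 0)) stop("Rates must be non-negative.", call. = FALSE)
  new_rate_profile(
    "piecewise_task",
    list(baseline = baseline, pre_cue = pre_cue, dip = dip,
         rebound = rebound),
    function(t) {
      r <- numeric(length(t))
      # ramp from baseline (1.8 s before cue) down to pre_cue at the cue
      u <- pmin(pmax((t + 1.8) / 1.8, 0), 1)
      r <- baseline + (pre_cue - baseline) * u
      # rapid post-cue inhibition and partial rebound
      r[t >= 0.00 & t < 0.10] <-
        pre_cue + (dip - pre_cue) * (t[t >= 0.00 & t < 0.10] - 0.00) / 0.10
      r[t >= 0.10 & t < 0.28] <- dip
      r[t >= 0.28 & t < 0.30] <-
        dip + (rebound - dip) * (t[t >= 0.28 & t < 0.30] - 0.28) / 0.02
      r[t >= 0.30] <- rebound
      r
    }
  )
}
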