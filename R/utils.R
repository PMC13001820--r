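# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so exported generators are pure functions of their
# arguments.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Uniform time grid at `rate_hz` spanning [t_from, t_to], built on integer
# sample indices so repeated calls share exact sample instants.
time_grid <- function(t_from, t_to, rate_hz) {
  i0 <- ceiling(round(t_from * rate_hz, 9))
  i1 <- floor(round(t_to * rate_hz, 9))
  (i0:i1) / rate_hz
}

# Reflect a free random walk into [-bound, bound] (triangle-wave folding);
# vectorised equivalent of reflecting each step at the boundary.
fold_reflect <- function(z, bound) {
  r <- (z + bound) %% (4 * bound)
  ifelse(r < 2 * bound, r - bound, 3 * bound - r)
}

# Smooth unit step used for injected saccade waveforms: minimum-jerk shape
# in [0, 1], clamped outside.
mj_step <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

`%||%` <- function(x, y) if (is.null(x)) y else x
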