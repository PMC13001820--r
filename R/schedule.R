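#' Task conditions
#'
#' The four trial conditions of the delayed-response task, in their canonical
#' order: passive fixation of the go cue, passive tracking of a cursor that
#' moves itself to the target, a reach with visible cursor feedback, and a
#' reach without cursor feedback.
#'
#' @return Character vector of the four condition labels.
#' @export
task_conditions <- function() {
  c("cue_monitoring", "cursor_tracking", "reach_visible", "reach_invisible")
}

#' Task geometry defaults
#'
#' Workspace geometry of the task: the hand start position at the origin, the
#' fixation/reach target 20 cm vertically above it, 2-cm start and target
#' discs, a 1-cm cursor, and a 37-cm viewing distance at which 1 cm on the
#' display subtends about 1.5 visual degrees.
#'
#' @return A named list with elements `start_position`, `target_position`
#'   (cm, `c(x, y)`), `target_diameter`, `start_diameter`, `cursor_diameter`
#'   (cm) and `viewing_distance` (cm).
#' @export
geometry_config <- function() {
  list(
    start_position  = c(0, 0),
    target_position = c(0, 20),
    target_diameter = 2,
    start_diameter  = 2,
    cursor_diameter = 1,
    viewing_distance = 37
  )
}

#' Build one trial's event schedule
#'
#' Times are measured from target appearance (`t_show_target = 0`). The go
#' cue follows after a delay drawn from 1.8--2.0 s; condition-specific
#' response phases start 0.3 s after the go cue for the two passive
#' conditions. `t_trial_end` is filled in by the simulator once the
#' condition-specific ending is known.
#'
#' @param condition One of [task_conditions()].
#' @param delay_duration Delay between target appearance and go cue, seconds;
#'   must lie in `[1.8, 2.0]`.
#' @param cursor_move_duration Cursor movement duration for the
#'   cursor-tracking condition, seconds in `[1.15, 1.35]`; ignored otherwise.
#' @param post_cue_delay Delay between go cue and response-phase start for
#'   the passive conditions, seconds (default 0.3).
#' @return A one-row tibble with columns `condition`, `t_show_target`,
#'   `t_go`, `t_trial_end` (NA until simulated), `delay_duration`,
#'   `post_cue_delay`, `cursor_move_duration`.
#' @export
event_schedule <- function(condition, delay_duration = 1.9,
                           cursor_move_duration = 1.25,
                           post_cue_delay = 0.3) {
  condition <- match.arg(condition, task_conditions())
  if (delay_duration < 1.8 || delay_duration > 2.0) {
    stop("`delay_duration` must lie in [1.8, 2.0] seconds.", call. = FALSE)
  }
  if (condition == "cursor_tracking" &&
      (cursor_move_duration < 1.15 || cursor_move_duration > 1.35)) {
    stop("`cursor_move_duration` must lie in [1.15, 1.35] seconds.",
         call. = FALSE)
  }
  tibble::tibble(
    condition = condition,
    t_show_target = 0,
    t_go = delay_duration,
    t_trial_end = NA_real_,
    delay_duration = delay_duration,
    post_cue_delay = post_cue_delay,
    cursor_move_duration = ifelse(condition == "cursor_tracking",
                                  cursor_move_duration, NA_real_)
  )
}
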