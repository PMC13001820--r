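#' Apply the trial-exclusion rules
#'
#' Four rules are applied sequentially, in their canonical order, and each
#' trial is attributed to the first rule it violates (so per-rule counts
#' sum to the total number of exclusions):
#'
#' 1. `rt_below_100ms_or_missing_eye` — the hand reaction time is below
#'    100 ms (reach conditions), or eye data are missing inside the
#'    analysis window;
#' 2. `fixation_start_late` — target fixation starts 100 ms or more after
#'    target appearance (or never starts);
#' 3. `fixation_end_early` — target fixation ends 100 ms or more before
#'    the end of the condition-specific analysis window;
#' 4. `landing_gt_6cm` — a detected saccade landed more than 6 cm from the
#'    target centre.
#'
#' @param trials A tibble of analysed trials carrying the derived columns
#'   `reaction_time` (s; `NA` for passive conditions), `eye_missing`
#'   (logical), `t_show_target`, `t_fix_start` (first gaze sample within
#'   6 cm of the target; `NA` if never), `t_fix_end` (last such sample
#'   inside the window), `t_window_end` (condition-specific end of the
#'   analysis window) and `landing_max_dist` (cm; largest detected saccade
#'   landing distance from the target, `NA` when no saccades).
#' @param max_landing_dist Landing-rule radius, cm (default 6).
#' @return A list: `retained` (the surviving rows, with `reason = "none"`),
#'   `excluded` (the removed rows with their `reason`), and `report`, a
#'   tibble with one row per rule (`rule`, `n_excluded`) plus attributes
#'   `n_input` and `n_retained`.
#' @export
apply_exclusions <- function(trials, max_landing_dist = 6) {
  required <- c("reaction_time", "eye_missing", "t_show_target",
                "t_fix_start", "t_fix_end", "t_window_end",
                "landing_max_dist")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("Trials lack derived column(s) ",
         paste(missing_cols, collapse = ", "),
         "; run the analysis stages before exclusion.", call. = FALSE)
  }
  rule1 <- (!is.na(trials$reaction_time) & trials$reaction_time < 0.1) |
    trials$eye_missing
  rule2 <- is.na(trials$t_fix_start) |
    (trials$t_fix_start - trials$t_show_target) >= 0.1
  rule3 <- is.na(trials$t_fix_end) |
    (trials$t_window_end - trials$t_fix_end) >= 0.1
  rule4 <- !is.na(trials$landing_max_dist) &
    trials$landing_max_dist > max_landing_dist

  reason <- rep("none", nrow(trials))
  reason[rule4] <- "landing_gt_6cm"
  reason[rule3] <- "fixation_end_early"
  reason[rule2] <- "fixation_start_late"
  reason[rule1] <- "rt_below_100ms_or_missing_eye"
  trials$reason <- reason

  report <- tibble::tibble(
    rule = exclusion_rules(),
    n_excluded = vapply(exclusion_rules(),
                        function(r) sum(reason == r), integer(1),
                        USE.NAMES = FALSE)
  )
  attr(report, "n_input") <- nrow(trials)
  attr(report, "n_retained") <- sum(reason == "none")
  list(
    retained = trials[reason == "none", , drop = FALSE],
    excluded = trials[reason != "none", , drop = FALSE],
    report = report
  )
}
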