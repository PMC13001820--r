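#' Write a simulated dataset to plain-text trial files
#'
#' Writes one delimited file plus one JSON sidecar per trial. The delimited
#' file has columns `time_s, eye_x_cm, eye_y_cm, hand_x_cm, hand_y_cm,
#' cursor_x_cm, cursor_y_cm` on the 1000-Hz hand time base; eye columns are
#' empty at instants the 500-Hz eye tracker did not sample and at missing
#' (blink) samples, and cursor columns are empty when no cursor was shown.
#' The sidecar records the condition, the event schedule, the ground-truth
#' kinematic landmarks, the planted violation and the injected
#' microsaccades, plus the exact gaze grid (`gaze_t0`, `gaze_n`) so missing
#' eye samples can be distinguished from unsampled instants on re-read.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of delimited-file paths.
#' @export
write_trials <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    row <- dataset[i, ]
    stem <- sprintf("%s_%s_%03d", row$participant, row$condition, row$trial)
    gaze <- row$gaze[[1]]
    hand <- row$hand[[1]]
    cursor <- row$cursor[[1]]
    tt <- hand$time
    ei <- match(round(gaze$time * 1000), round(tt * 1000))
    eye_x <- eye_y <- rep(NA_real_, length(tt))
    keep <- !is.na(ei)
    eye_x[ei[keep]] <- gaze$x[keep]
    eye_y[ei[keep]] <- gaze$y[keep]
    tab <- tibble::tibble(
      time_s = tt, eye_x_cm = eye_x, eye_y_cm = eye_y,
      hand_x_cm = hand$x, hand_y_cm = hand$y,
      cursor_x_cm = if (is.null(cursor)) NA_real_ else cursor$x,
      cursor_y_cm = if (is.null(cursor)) NA_real_ else cursor$y
    )
    paths[i] <- file.path(dir, paste0(stem, ".csv"))
    readr::write_csv(tab, paths[i], na = "")
    meta <- list(
      participant = row$participant, condition = row$condition,
      trial = row$trial, t_show_target = row$t_show_target,
      t_go = row$t_go, t_trial_end = row$t_trial_end,
      post_cue_delay = row$post_cue_delay,
      cursor_move_duration = row$cursor_move_duration,
      violation = row$violation, rt_true = row$rt_true,
      move_duration_true = row$move_duration_true,
      hand_onset_true = row$hand_onset_true,
      hand_offset_true = row$hand_offset_true,
      t_fix_start_true = row$t_fix_start_true,
      gaze_t0 = gaze$time[1], gaze_n = nrow(gaze),
      events_true = row$events_true[[1]]
    )
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(paths)
}

#' Read a trial dataset written by [write_trials()]
#'
#' @param dir Directory containing `*.csv` / `*.json` trial pairs.
#' @return A tibble with the same columns as [generate_dataset()].
#' @export
read_trials <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(csvs) == 0) stop("No trial files found in `dir`.", call. = FALSE)
  rows <- lapply(csvs, function(path) {
    meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                                simplifyVector = TRUE)
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    gt <- meta$gaze_t0 + (seq_len(meta$gaze_n) - 1) / 500
    gi <- match(round(gt * 1000), round(tab$time_s * 1000))
    gaze <- tibble::tibble(time = gt,
                           x = tab$eye_x_cm[gi], y = tab$eye_y_cm[gi])
    hand <- tibble::tibble(time = tab$time_s,
                           x = tab$hand_x_cm, y = tab$hand_y_cm)
    cursor <- if (all(is.na(tab$cursor_x_cm))) NULL else
      tibble::tibble(time = tab$time_s,
                     x = tab$cursor_x_cm, y = tab$cursor_y_cm)
    ev <- meta$events_true
    ev <- if (is.null(ev) || length(ev) == 0) {
      tibble::tibble(t_onset = numeric(), t_offset = numeric(),
                     duration = numeric(), amplitude = numeric(),
                     peak_velocity = numeric(), direction = numeric())
    } else {
      tibble::as_tibble(ev)
    }
    tibble::tibble(
      participant = meta$participant, condition = meta$condition,
      trial = meta$trial, t_show_target = meta$t_show_target,
      t_go = meta$t_go, t_trial_end = meta$t_trial_end,
      post_cue_delay = meta$post_cue_delay,
      cursor_move_duration = meta$cursor_move_duration %||% NA_real_,
      violation = meta$violation,
      rt_true = meta$rt_true %||% NA_real_,
      move_duration_true = meta$move_duration_true %||% NA_real_,
      hand_onset_true = meta$hand_onset_true %||% NA_real_,
      hand_offset_true = meta$hand_offset_true %||% NA_real_,
      t_fix_start_true = meta$t_fix_start_true,
      gaze = list(gaze), hand = list(hand), cursor = list(cursor),
      events_true = list(ev)
    )
  })
  dplyr::bind_rows(rows)
}
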