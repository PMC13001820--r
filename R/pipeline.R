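#' Pipeline run configuration
#'
#' Collects every pipeline parameter with the task's values as defaults:
#' detection multiplier `lambda = 5` and 40-ms minimum duration, the
#' printed zone set, 20-cm reach amplitude, 1.8--2.0-s delays and the
#' 0.3-s post-cue delay (both inside [sim_config()]), and the 50-ms-peak
#' causal kernel.
#'
#' @param out_dir Run directory for [run_pipeline()] outputs.
#' @param sim A [sim_config()].
#' @param n_participants,n_trials_per_condition Dataset size.
#' @param lambda,min_duration Detector parameters (SD multiplier; seconds).
#' @param alpha Causal-kernel parameter, 1/s.
#' @param rate_method `"state_based"` or `"causal_kernel"`.
#' @param zones Fixed zones to summarise (default all).
#' @param seed Integer seed for the simulation.
#' @param write_trial_files Write per-trial delimited files into the run
#'   directory (default FALSE; they are large).
#' @param verbose Print stage progress.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("reachsacc_run_"),
                       sim = sim_config(),
                       n_participants = 17, n_trials_per_condition = 60,
                       lambda = 5, min_duration = 0.040, alpha = 1 / 0.05,
                       rate_method = "state_based",
                       zones = zone_definitions()$zone,
                       seed = 1, write_trial_files = FALSE,
                       verbose = TRUE) {
  cfg <- list(out_dir = out_dir, sim = sim,
              n_participants = n_participants,
              n_trials_per_condition = n_trials_per_condition,
              lambda = lambda, min_duration = min_duration, alpha = alpha,
              rate_method = rate_method, zones = zones, seed = seed,
              write_trial_files = write_trial_files, verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config A [run_config()].
#' @return Invisibly `TRUE`; otherwise an error listing every offending
#'   field.
#' @export
validate_run_config <- function(config) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(inherits(config, "run_config"), "not a run_config object")
  chk(is.numeric(config$lambda) && config$lambda > 0,
      "lambda: must be > 0")
  chk(is.numeric(config$min_duration) && config$min_duration > 0,
      "min_duration: must be > 0")
  chk(is.numeric(config$alpha) && config$alpha > 0, "alpha: must be > 0")
  chk(config$rate_method %in% c("state_based", "causal_kernel"),
      "rate_method: unknown method")
  chk(all(config$zones %in% zone_definitions()$zone),
      "zones: unknown zone name")
  chk(config$n_participants >= 1, "n_participants: must be >= 1")
  chk(config$n_trials_per_condition >= 1,
      "n_trials_per_condition: must be >= 1")
  chk(is.numeric(config$seed) && is.finite(config$seed),
      "seed: must be a finite number")
  chk(inherits(config$sim, "sim_config"), "sim: must be a sim_config")
  if (length(bad) > 0) {
    stop("Invalid run configuration:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' simulate -> preprocess/detect/segment -> exclude -> rates/zones ->
#' statistics -> report, writing all intermediates and a structured run
#' log into `config$out_dir`. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `dataset`, `analyzed`, `excl`
#'   (exclusion result), `zone_tab`, `stats`, and the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = config$seed,
              parameters = config[c("n_participants",
                                    "n_trials_per_condition", "lambda",
                                    "min_duration", "alpha", "rate_method",
                                    "zones")])
  say <- function(...) if (isTRUE(config$verbose)) message(...)

  say("simulate: ", config$n_participants, " participants x 4 x ",
      config$n_trials_per_condition, " trials")
  dataset <- generate_dataset(config$sim, config$n_participants,
                              config$n_trials_per_condition, config$seed)
  if (isTRUE(config$write_trial_files)) {
    write_trials(dataset, file.path(config$out_dir, "trials"))
  }

  say("analyze: preprocessing, detection, segmentation")
  analyzed <- analyze_trials(dataset, lambda = config$lambda,
                             min_duration = config$min_duration)

  say("exclude: applying the four trial-exclusion rules")
  excl <- apply_exclusions(analyzed)
  readr::write_csv(excl$report, file.path(config$out_dir,
                                          "exclusion_report.csv"))

  say("rates: ", config$rate_method, " zone summaries")
  zone_tab <- zone_summaries(excl$retained, method = config$rate_method,
                             zones = config$zones, alpha = config$alpha)
  readr::write_csv(zone_tab, file.path(config$out_dir, "zone_rates.csv"))

  say("stats: condition-level ANOVAs and post hocs")
  rt_tab <- excl$retained |>
    dplyr::filter(.data$condition %in%
                    c("reach_visible", "reach_invisible")) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(reaction_time = mean(.data$reaction_time,
                                          na.rm = TRUE),
                     .groups = "drop")
  stats <- condition_stats(zone_tab, rt_tab = rt_tab)

  build_report(list(analyzed = excl$retained, zone_tab = zone_tab,
                    stats = stats, excl = excl, config = config),
               config$out_dir)
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  log$n_trials <- nrow(dataset)
  log$n_retained <- attr(excl$report, "n_retained")
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, analyzed = analyzed, excl = excl,
                 zone_tab = zone_tab, stats = stats,
                 out_dir = config$out_dir))
}

#' Write report tables and figures
#'
#' Emits delimited statistics tables, an aligned rate-curve figure (one
#' curve per condition) and a zone-bar figure into `dir`. Deterministic
#' given its inputs.
#'
#' @param results List with `analyzed` (retained analysed trials),
#'   `zone_tab`, `stats` (from [condition_stats()]) and optionally `excl`
#'   and `config`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
build_report <- function(results, dir) {
  if (is.null(results$zone_tab) || nrow(results$zone_tab) == 0) {
    stop("Empty results; nothing to report.", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, p)
  }
  st <- results$stats
  if (!is.null(st)) {
    w(tidy.rm_anova(st$zone_by_condition), "anova_zone_by_condition.csv")
    w(tidy.rm_anova(st$cue_inhibition), "anova_cue_inhibition.csv")
    ow <- purrr::imap_dfr(st$one_way, function(a, z) {
      dplyr::mutate(tidy.rm_anova(a), zone = z, .before = 1)
    })
    w(ow, "anova_one_way_by_zone.csv")
    ph <- purrr::imap_dfr(st$posthoc, function(p, z) {
      dplyr::mutate(p$letters, zone = z, .before = 1)
    })
    w(ph, "posthoc_letters.csv")
    if (!is.null(st$rt_test)) w(st$rt_test, "rt_paired_t.csv")
  }

  # figures: aligned rate curves per condition, and zone bars
  analyzed <- results$analyzed
  if (!is.null(analyzed) && nrow(analyzed) > 0) {
    curves <- analyzed |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_map(function(sub, key) {
        rs <- rate_state_method(sub)
        tibble::tibble(condition = key$condition, t = rs$t, rate = rs$rate)
      }) |>
      dplyr::bind_rows()
    g1 <- ggplot2::ggplot(curves,
                          ggplot2::aes(x = .data$t, y = .data$rate,
                                       colour = .data$condition)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time relative to go cue (s)",
                    y = "microsaccade rate (Hz)") +
      ggplot2::theme_minimal()
    p1 <- file.path(dir, "rate_curves.png")
    ggplot2::ggsave(p1, g1, width = 7, height = 4, dpi = 150)
    paths <- c(paths, p1)
  }
  g2 <- plot_zone_rates(results$zone_tab)
  p2 <- file.path(dir, "zone_rates.png")
  ggplot2::ggsave(p2, g2, width = 8, height = 5, dpi = 150)
  paths <- c(paths, p2)
  invisible(paths)
}
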