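#' Plot a microsaccade-rate time course
#'
#' Rate (Hz) against time relative to the go cue, with the fixed analysis
#' zones shaded.
#'
#' @param object A `rate_series` from [rate_state_method()] or
#'   [rate_kernel_method()].
#' @param shade_zones Zone names to shade (default the three headline
#'   zones).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_series
#' @export
autoplot.rate_series <- function(object,
                                 shade_zones = c("initial_fixation",
                                                 "pre_cue_250",
                                                 "post_inhibition"),
                                 ...) {
  zd <- zone_definitions()
  zd <- zd[zd$zone %in% shade_zones, ]
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$rate))
  if (nrow(zd) > 0) {
    g <- g + ggplot2::geom_rect(
      data = zd, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6
    )
  }
  g +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to go cue (s)",
                  y = "microsaccade rate (Hz)",
                  title = paste0("Microsaccade rate (",
                                 attr(object, "method"), ")")) +
    ggplot2::theme_minimal()
}

#' Zone-by-condition bar chart of mean rates
#'
#' One panel per zone; bars are condition means across participants with
#' standard-error bars.
#'
#' @param zone_tab Tibble from [zone_summaries()].
#' @param zones Zones to show (default the four headline zones).
#' @return A ggplot object.
#' @export
plot_zone_rates <- function(zone_tab,
                            zones = c("initial_fixation", "pre_cue_250",
                                      "post_inhibition", "movement")) {
  zones <- intersect(zones, unique(zone_tab$zone))
  sub <- zone_tab[zone_tab$zone %in% zones, ]
  summ <- sub |>
    dplyr::group_by(.data$zone, .data$condition) |>
    dplyr::summarise(mean = mean(.data$mean_rate),
                     se = stats::sd(.data$mean_rate) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$condition, y = .data$mean,
                               fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3) +
    ggplot2::facet_wrap(~zone, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "microsaccade rate (Hz)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1),
                   legend.position = "none")
}
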