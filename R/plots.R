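#' Bland-Altman plot of paired measurements
#'
#' Difference against pair mean, one panel per variable, with the bias
#' and the 95% limits of agreement as horizontal reference lines.
#'
#' @param pairs Paired measurements from [build_daily_pairs()].
#' @param loa Optional `loa_rm` fit; computed from `pairs` if missing.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, loa = NULL) {
  check_columns(pairs, c("variable", "watch_value", "gold_value",
                         "difference"), "`pairs`")
  loa <- loa %||% loa_repeated(pairs)
  lines <- loa$summary |>
    dplyr::select("variable", "bias", "loa_low", "loa_high") |>
    tidyr::pivot_longer(!"variable", names_to = "line", values_to = "y")
  pairs |>
    dplyr::mutate(pair_mean = (.data$watch_value + .data$gold_value) / 2) |>
    ggplot2::ggplot(ggplot2::aes(.data$pair_mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y, linetype = .data$line),
      colour = "steelblue"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(bias = "solid", loa_low = "dashed", loa_high = "dashed"),
      guide = "none"
    ) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = "mean of the paired readings",
                  y = "difference (watch - gold)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_bland_altman
#' @param object A `loa_rm` object.
#' @param ... Unused.
#' @method autoplot loa_rm
#' @export
autoplot.loa_rm <- function(object, ...) {
  plot_bland_altman(object$pairs, object)
}

#' Mean hourly heart-rate curves per group
#'
#' @param profiles Long profiles from [hourly_profiles()].
#' @return A ggplot object.
#' @export
plot_hourly_profiles <- function(profiles) {
  curves <- group_hourly_curves(profiles)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$hour, .data$mean_hr,
                               colour = .data$group)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_hr - .data$se_hr,
                   ymax = .data$mean_hr + .data$se_hr,
                   fill = .data$group),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "hour of day", y = "mean heart rate (bpm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_hourly_profiles
#' @param object A `profile_manova` object.
#' @param ... Unused.
#' @method autoplot profile_manova
#' @export
autoplot.profile_manova <- function(object, ...) {
  plot_hourly_profiles(object$profiles)
}

#' Hypnogram plot of a sleep session
#'
#' Stage-over-time step display of one or both devices' records.
#'
#' @param intervals A four-stage interval tibble (possibly both devices).
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(intervals) {
  check_columns(intervals, c("device", "start", "end", "stage"),
                "`intervals`")
  levels <- c("deep", "light", "REM", "awake")
  intervals |>
    dplyr::mutate(stage = factor(.data$stage, levels = levels)) |>
    ggplot2::ggplot() +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$stage, yend = .data$stage,
                   colour = .data$stage),
      linewidth = 3
    ) +
    ggplot2::facet_wrap(~device, ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
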