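#' Per-volunteer mean vitals across visits
#'
#' Averages each volunteer's consolidated daily values across available
#' days, separately per variable and device (unweighted mean; a
#' single-day volunteer contributes that day's value).
#'
#' @param pairs Paired daily measurements from [build_daily_pairs()].
#' @param roster Optional roster (`volunteer_id`, `group`) to attach the
#'   study group.
#' @return A tibble `volunteer_id`, (`group`,) `variable`, `device`,
#'   `mean_value`, `n_days`.
#' @export
volunteer_means <- function(pairs, roster = NULL) {
  check_columns(pairs, c("volunteer_id", "variable", "watch_value",
                         "gold_value"), "`pairs`")
  long <- pairs |>
    tidyr::pivot_longer(c("watch_value", "gold_value"),
                        names_to = "device", values_to = "value") |>
    dplyr::mutate(device = sub("_value$", "", .data$device)) |>
    dplyr::group_by(.data$volunteer_id, .data$variable, .data$device) |>
    dplyr::summarise(mean_value = mean(.data$value), n_days = dplyr::n(),
                     .groups = "drop")
  if (!is.null(roster)) {
    check_columns(roster, c("volunteer_id", "group"), "`roster`")
    long <- dplyr::inner_join(long,
                              dplyr::select(roster, "volunteer_id", "group"),
                              by = "volunteer_id") |>
      dplyr::relocate("group", .after = "volunteer_id")
  }
  long
}

#' Compare the study groups on mean vitals
#'
#' Welch two-sample two-tailed t tests of the per-volunteer means between
#' the two groups, per variable, carried out separately for each device's
#' data. p values are Holm-adjusted across the variables within each
#' device.
#'
#' @param means Output of [volunteer_means()] including a `group` column.
#' @return A tibble per variable and device with group means and SDs,
#'   `t`, `df`, `p_value` and `p_adj`.
#' @export
compare_groups <- function(means) {
  check_columns(means, c("volunteer_id", "group", "variable", "device",
                         "mean_value"), "`means`")
  groups <- sort(unique(means$group))
  if (length(groups) != 2) abort("`means` must contain exactly 2 groups")
  out <- means |>
    dplyr::group_by(.data$device, .data$variable) |>
    dplyr::group_modify(function(df, key) {
      x <- df$mean_value[df$group == groups[1]]
      y <- df$mean_value[df$group == groups[2]]
      if (length(x) < 2 || length(y) < 2) {
        abort("each group needs at least 2 volunteers")
      }
      tt <- t.test(x, y, var.equal = FALSE)
      tibble::tibble(
        group1 = groups[1], mean1 = mean(x), sd1 = sd(x), n1 = length(x),
        group2 = groups[2], mean2 = mean(y), sd2 = sd(y), n2 = length(y),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
    }) |>
    dplyr::group_by(.data$device) |>
    dplyr::mutate(p_adj = p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup()
  out
}

#' Hourly heart-rate profiles per volunteer
#'
#' Reduces the weekday continuous heart-rate stream to one 24-position
#' vector per volunteer: readings are first averaged within each
#' (day, clock hour) cell and those daily hourly means are then averaged
#' across days, hour by hour. Volunteers lacking data in any of the 24
#' hours cannot enter the multivariate profile analysis; they are dropped
#' and listed in the `dropped` attribute.
#'
#' @param records Weekday-filtered continuous heart-rate records
#'   (`volunteer_id`, `timestamp`, `value`).
#' @param roster Roster with `volunteer_id` and `group`.
#' @return A long tibble `volunteer_id`, `group`, `hour` (0-23), `hr`,
#'   complete in `hour` for every retained volunteer, with a `dropped`
#'   attribute naming excluded volunteers.
#' @export
hourly_profiles <- function(records, roster) {
  check_columns(records, c("volunteer_id", "timestamp", "value"), "`records`")
  check_columns(roster, c("volunteer_id", "group"), "`roster`")
  ts <- as_wall_clock(records$timestamp)
  per_hour <- records |>
    dplyr::mutate(date = as.Date(ts), hour = as.integer(format(ts, "%H"))) |>
    dplyr::group_by(.data$volunteer_id, .data$date, .data$hour) |>
    dplyr::summarise(hr = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$volunteer_id, .data$hour) |>
    dplyr::summarise(hr = mean(.data$hr), .groups = "drop")
  coverage <- dplyr::count(per_hour, .data$volunteer_id)
  dropped <- coverage$volunteer_id[coverage$n < 24]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " volunteer(s) without full 24-hour coverage dropped"))
  }
  out <- per_hour |>
    dplyr::filter(!.data$volunteer_id %in% dropped) |>
    dplyr::inner_join(dplyr::select(roster, "volunteer_id", "group"),
                      by = "volunteer_id") |>
    dplyr::select("volunteer_id", "group", "hour", "hr") |>
    dplyr::arrange(.data$volunteer_id, .data$hour)
  attr(out, "dropped") <- dropped
  out
}

#' Mean hourly heart-rate curve per group
#'
#' Plot-ready export of the average 24-hour curve of each group
#' (mean and standard error across volunteers per clock hour).
#'
#' @param profiles Output of [hourly_profiles()].
#' @return A tibble `group`, `hour`, `mean_hr`, `se_hr`, `n`.
#' @export
group_hourly_curves <- function(profiles) {
  check_columns(profiles, c("group", "hour", "hr"), "`profiles`")
  profiles |>
    dplyr::group_by(.data$group, .data$hour) |>
    dplyr::summarise(mean_hr = mean(.data$hr),
                     se_hr = sd(.data$hr) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
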