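#' Simulate daily paired triplicate visits
#'
#' For every volunteer-day and variable a latent true value is drawn
#' around the volunteer-level mean; the gold-standard device records a
#' triplicate of that value plus replicate noise, and the smartwatch
#' records a triplicate with the configured additive offset, the linear
#' error trend `slope * (true - center)` (blood pressures), a day-level
#' device error shared by the three replicates, and replicate noise. With
#' probability `outlier_prob` one replicate of a triplicate is perturbed
#' by `outlier_frac` of its value (random sign). SpO2 readings are capped
#' at the configured ceiling after all noise, reproducing the fan-shaped
#' difference pattern near 100%.
#'
#' @param roster A volunteer roster from [sim_cohort()].
#' @param config A [sim_config()] object.
#' @return A tibble of vital records: `volunteer_id`, `timestamp`, `date`,
#'   `variable`, `value`, `device` (`"watch"`/`"gold"`), `mode`
#'   (`"manual"`), `replicate`.
#' @examples
#' cfg <- sim_config(seed = 1, n_per_group = 2, days = 2)
#' sim_paired_visits(sim_cohort(cfg), cfg)
#' @export
sim_paired_visits <- function(roster, config) {
  stopifnot(inherits(config, "wear_config"))
  if (nrow(roster) == 0) abort("`roster` must contain at least one volunteer")
  check_columns(roster, c("volunteer_id", "group"), "`roster`")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config, "visits"))

  vol_level <- tidyr::crossing(
    dplyr::select(roster, "volunteer_id", "group"),
    config$vitals
  ) |>
    dplyr::mutate(
      vol_mean = .data$mu +
        ifelse(.data$group == "covid", 0.5, -0.5) * .data$group_shift +
        rnorm(dplyr::n(), 0, .data$between_sd)
    )

  days <- tibble::tibble(date = config$start_date + seq_len(config$days) - 1)
  base <- tidyr::crossing(vol_level, days) |>
    dplyr::arrange(.data$volunteer_id, .data$variable, .data$date) |>
    dplyr::mutate(
      true = .data$vol_mean + rnorm(dplyr::n(), 0, .data$within_sd),
      trend = ifelse(is.na(.data$center), 0,
                     .data$slope * (.data$true - .data$center)),
      day_err = rnorm(dplyr::n(), 0, .data$day_sd)
    )

  one_device <- function(dev) {
    n <- nrow(base)
    hit <- runif(n) < config$outlier_prob
    out_idx <- sample.int(3, n, replace = TRUE)
    out_sign <- sample(c(-1, 1), n, replace = TRUE)
    tidyr::crossing(
      dplyr::mutate(base, .row = dplyr::row_number()),
      replicate = 1:3
    ) |>
      dplyr::mutate(
        device = dev,
        noise_sd = if (dev == "gold") .data$gold_sd else .data$watch_sd,
        value = if (dev == "gold") {
          .data$true + rnorm(dplyr::n(), 0, .data$noise_sd)
        } else {
          .data$true + .data$bias + .data$trend + .data$day_err +
            rnorm(dplyr::n(), 0, .data$noise_sd)
        },
        outlier = hit[.data$.row] & .data$replicate == out_idx[.data$.row],
        value = ifelse(.data$outlier,
                       .data$value *
                         (1 + out_sign[.data$.row] * config$outlier_frac),
                       .data$value)
      )
  }

  records <- dplyr::bind_rows(one_device("gold"), one_device("watch")) |>
    dplyr::mutate(
      value = ifelse(.data$variable == "spo2",
                     pmin(.data$value, config$spo2_ceiling), .data$value),
      value = pmax(.data$value, 1),
      timestamp = as_wall_clock(.data$date) + 9 * 3600 +
        (.data$replicate - 1) * 60,
      mode = "manual"
    ) |>
    dplyr::arrange(.data$volunteer_id, .data$date, .data$variable,
                   .data$device, .data$replicate)
  dplyr::select(records, "volunteer_id", "timestamp", "date", "variable",
                "value", "device", "mode", "replicate")
}

# circadian heart-rate template (bpm deviation from baseline) at
# fractional hour-of-day h: morning and post-lunch Gaussian bumps plus a
# circular nocturnal trough
circadian_template <- function(h, hr) {
  circ <- function(x, center) pmin(abs(x - center), 24 - abs(x - center))
  hr$morning_amp * exp(-0.5 * ((h - hr$morning_hour) / hr$morning_width)^2) +
    hr$lunch_amp * exp(-0.5 * ((h - hr$lunch_hour) / hr$lunch_width)^2) -
    hr$night_dip * exp(-0.5 * (circ(h, hr$trough_hour) / hr$night_width)^2)
}

#' Simulate the continuous heart-rate stream
#'
#' Produces a minute-level (or coarser, see `hr_step_min`) heart-rate
#' stream per volunteer-day following the circadian template: a rise at
#' the beginning of work hours (around 6-8 h), a post-lunch peak (13-14 h)
#' and a nocturnal trough, plus a volunteer-level baseline offset and
#' residual noise. Days run consecutively from `start_date`, so the
#' stream spans weekdays and weekends and exercises the weekday filter.
#'
#' @inheritParams sim_paired_visits
#' @return A tibble of continuous records: `volunteer_id`, `timestamp`,
#'   `variable` (`"hr"`), `value`, `device` (`"watch"`), `mode`
#'   (`"continuous"`).
#' @export
sim_continuous_hr <- function(roster, config) {
  stopifnot(inherits(config, "wear_config"))
  if (nrow(roster) == 0) abort("`roster` must contain at least one volunteer")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config, "hr"))
  hr <- config$hr

  baseline <- dplyr::select(roster, "volunteer_id", "group") |>
    dplyr::mutate(
      baseline = hr$baseline + hr$group_effect * (.data$group == "covid") +
        rnorm(dplyr::n(), 0, hr$baseline_sd)
    )

  step_s <- config$hr_step_min * 60
  offsets <- seq(0, config$hr_days * 86400 - step_s, by = step_s)
  day0 <- as_wall_clock(config$start_date)
  stream <- tidyr::crossing(baseline, offset = offsets) |>
    dplyr::mutate(
      timestamp = day0 + .data$offset,
      hour_frac = (.data$offset %% 86400) / 3600,
      value = pmax(.data$baseline + circadian_template(.data$hour_frac, hr) +
                     rnorm(dplyr::n(), 0, hr$resid_sd), 1),
      variable = "hr", device = "watch", mode = "continuous"
    )
  dplyr::select(stream, "volunteer_id", "timestamp", "variable", "value",
                "device", "mode")
}
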