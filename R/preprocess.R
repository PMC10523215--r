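VIABILITY_LIMITS <- tibble::tribble(
  ~variable, ~lo, ~hi,
  "spo2", 60, 100,
  "sbp", 20, 300,
  "dbp", 20, 300,
  "hr", 20, 300
)

#' Filter records to the biologically viable range
#'
#' Readings outside biological viability are treated as human or device
#' error and excluded before any analysis: SpO2 is kept in \[60, 100\]%,
#' blood pressures and heart rate in \[20, 300\] (mm Hg / bpm). The
#' per-variable exclusion tally is attached as the `exclusion_tally`
#' attribute (also retrievable with [exclusion_tally()]).
#'
#' @param records A tibble with at least `variable` and `value` columns.
#' @return The kept records, with an `exclusion_tally` attribute.
#' @examples
#' rec <- tibble::tibble(variable = c("spo2", "spo2", "hr"),
#'                       value = c(59.9, 97, 301))
#' kept <- filter_viable(rec)
#' exclusion_tally(kept)
#' @export
filter_viable <- function(records) {
  check_columns(records, c("variable", "value"), "`records`")
  check_variables(records$variable)
  if (any(!is.finite(records$value))) {
    abort(paste0("non-finite value(s) at row(s) ",
                 paste(head(which(!is.finite(records$value)), 5),
                       collapse = ", ")))
  }
  joined <- dplyr::left_join(records, VIABILITY_LIMITS, by = "variable")
  keep <- joined$value >= joined$lo & joined$value <= joined$hi
  tally <- tibble::tibble(variable = VIABILITY_LIMITS$variable) |>
    dplyr::left_join(
      dplyr::count(records[!keep, , drop = FALSE], .data$variable,
                   name = "excluded"),
      by = "variable"
    ) |>
    dplyr::mutate(excluded = dplyr::coalesce(.data$excluded, 0L))
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusion_tally") <- tally
  out
}

#' @rdname filter_viable
#' @param x A tibble returned by [filter_viable()].
#' @export
exclusion_tally <- function(x) {
  attr(x, "exclusion_tally") %||%
    abort("no exclusion tally attached; was this produced by filter_viable()?")
}

#' Keep weekday records from the continuous stream
#'
#' Continuously acquired data are restricted to Monday-Friday, since
#' weekday routines are more comparable across volunteers than weekends.
#' The filter is scoped to continuous-mode records: manual readings on
#' weekends are kept.
#'
#' @param records A tibble with `timestamp` and `mode` columns.
#' @return The filtered tibble.
#' @export
filter_weekdays <- function(records) {
  check_columns(records, c("timestamp", "mode"), "`records`")
  wd <- iso_weekday(as_wall_clock(records$timestamp))
  records[records$mode != "continuous" | wd <= 5, , drop = FALSE]
}

#' Consolidate one triplicate by the tolerance-region rules
#'
#' Three same-session replicates are reduced to a single value. With the
#' replicates sorted ascending (v1 <= v2 <= v3), the tolerance region is
#' TR = 10% of the smallest replicate, and the first matching rule
#' applies: (a) the whole range v3 - v1 lies within TR — average all
#' three (`all_within`); (b) both gaps v2 - v1 and v3 - v2 lie within TR
#' — keep the middle value (`middle_only`); (c) exactly one gap lies
#' within TR — average the middle value with that extreme
#' (`pair_with_extreme`); (d) otherwise the spread is taken as genuine
#' and all three are averaged (`none_within`). Comparisons are strict
#' (`< TR`); ties fall through to the next rule.
#'
#' @param values Exactly three finite replicate values.
#' @return A list with `value` and `case_label`.
#' @examples
#' consolidate_triple(c(90, 92, 105))  # 91, pair_with_extreme
#' @export
consolidate_triple <- function(values) {
  if (length(values) != 3 || anyNA(values)) {
    abort("a triplicate must contain exactly three non-missing values")
  }
  v <- sort(values)
  tr <- 0.10 * v[1]
  lo_gap <- v[2] - v[1] < tr
  hi_gap <- v[3] - v[2] < tr
  if (v[3] - v[1] < tr) {
    list(value = mean(v), case_label = "all_within")
  } else if (lo_gap && hi_gap) {
    list(value = v[2], case_label = "middle_only")
  } else if (lo_gap) {
    list(value = mean(v[1:2]), case_label = "pair_with_extreme")
  } else if (hi_gap) {
    list(value = mean(v[2:3]), case_label = "pair_with_extreme")
  } else {
    list(value = mean(v), case_label = "none_within")
  }
}

#' Consolidate all daily triplicates in a record table
#'
#' Groups manual records by volunteer, date, variable and device and
#' applies [consolidate_triple()] to each group, yielding one value per
#' volunteer-day-variable-device. Groups that do not contain exactly
#' three viable readings are dropped; their count is attached as the
#' `dropped_incomplete` attribute.
#'
#' @param records Viability-filtered manual records with columns
#'   `volunteer_id`, `timestamp` (or `date`), `variable`, `value`,
#'   `device`.
#' @return A tibble with `volunteer_id`, `date`, `variable`, `device`,
#'   `value`, `case_label`.
#' @export
consolidate_triplicates <- function(records) {
  check_columns(records, c("volunteer_id", "variable", "value", "device"),
                "`records`")
  if (!"date" %in% names(records)) {
    check_columns(records, "timestamp", "`records`")
    records$date <- as.Date(as_wall_clock(records$timestamp))
  }
  grouped <- records |>
    dplyr::group_by(.data$volunteer_id, .data$date, .data$variable,
                    .data$device) |>
    dplyr::summarise(values = list(.data$value), n = dplyr::n(),
                     .groups = "drop")
  incomplete <- sum(grouped$n != 3)
  if (incomplete > 0) {
    inform(paste0("dropping ", incomplete,
                  " volunteer-day group(s) without exactly 3 readings"))
  }
  out <- grouped |>
    dplyr::filter(.data$n == 3) |>
    dplyr::mutate(consolidated = purrr::map(.data$values, consolidate_triple),
                  value = purrr::map_dbl(.data$consolidated, "value"),
                  case_label = purrr::map_chr(.data$consolidated,
                                              "case_label")) |>
    dplyr::select("volunteer_id", "date", "variable", "device", "value",
                  "case_label")
  attr(out, "dropped_incomplete") <- incomplete
  out
}

#' Pair the consolidated daily values of the two devices
#'
#' Inner-joins the consolidated watch and gold values on volunteer, date
#' and variable and computes the difference `d = watch - gold`, so a
#' positive difference means the smartwatch overestimated. Days observed
#' by only one device yield no pair; duplicate keys violate the
#' one-value-per-day contract and raise an error.
#'
#' @param consolidated Output of [consolidate_triplicates()] (both
#'   devices).
#' @return A tibble of paired measurements: `volunteer_id`, `date`,
#'   `variable`, `watch_value`, `gold_value`, `difference`.
#' @export
build_daily_pairs <- function(consolidated) {
  check_columns(consolidated,
                c("volunteer_id", "date", "variable", "device", "value"),
                "`consolidated`")
  dups <- consolidated |>
    dplyr::count(.data$volunteer_id, .data$date, .data$variable,
                 .data$device) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dups) > 0) {
    abort(paste0("duplicate consolidated values for ", nrow(dups),
                 " volunteer-day-variable-device key(s); one per day expected"))
  }
  wide <- consolidated |>
    dplyr::select("volunteer_id", "date", "variable", "device", "value") |>
    tidyr::pivot_wider(names_from = "device", values_from = "value")
  for (col in c("watch", "gold")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide |>
    dplyr::filter(!is.na(.data$watch), !is.na(.data$gold)) |>
    dplyr::transmute(.data$volunteer_id, .data$date, .data$variable,
                     watch_value = .data$watch, gold_value = .data$gold,
                     difference = .data$watch - .data$gold)
}

#' Read and write vital-record tables
#'
#' The on-disk dialect is a plain CSV with columns `volunteer_id`,
#' `timestamp` (ISO 8601, local wall-clock), `variable`
#' (`spo2`/`sbp`/`dbp`/`hr`), `value`, `device` (`watch`/`gold`) and
#' `mode` (`manual`/`continuous`).
#'
#' @param file Path to a CSV file.
#' @return `read_vital_records()` returns a tibble of records.
#' @export
read_vital_records <- function(file) {
  out <- readr::read_csv(
    file,
    col_types = readr::cols(
      volunteer_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      variable = readr::col_character(),
      value = readr::col_double(),
      device = readr::col_character(),
      mode = readr::col_character()
    )
  )
  check_columns(out, c("volunteer_id", "timestamp", "variable", "value",
                       "device", "mode"), "vital-record CSV")
  check_variables(out$variable)
  out
}

#' @rdname read_vital_records
#' @param records A tibble of vital records.
#' @export
write_vital_records <- function(records, file) {
  check_columns(records, c("volunteer_id", "timestamp", "variable", "value",
                           "device", "mode"), "`records`")
  readr::write_csv(
    dplyr::select(records, "volunteer_id", "timestamp", "variable", "value",
                  "device", "mode"),
    file
  )
  invisible(file)
}
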