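#' Default vital-sign alert rules
#'
#' Threshold triggers used by the telemonitoring dashboard: systolic
#' blood pressure at or below 70 or above 180 mm Hg; diastolic at or
#' below 40 or above 120 mm Hg; oxygen saturation below 88%; heart rate
#' at or below 40 bpm. Comparators are `"le"`, `"lt"`, `"ge"`, `"gt"`
#' and every threshold is overridable, so alternative boundary readings
#' of the same rules can be configured.
#'
#' @param sbp_low,sbp_high,dbp_low,dbp_high,spo2_low,hr_low Rule
#'   thresholds in the variable's units.
#' @return A rules tibble with columns `label`, `variable`, `comparator`,
#'   `threshold`.
#' @export
alert_rules <- function(sbp_low = 70, sbp_high = 180,
                        dbp_low = 40, dbp_high = 120,
                        spo2_low = 88, hr_low = 40) {
  tibble::tribble(
    ~label,                ~variable, ~comparator, ~threshold,
    "sbp_minima",          "sbp",     "le",        sbp_low,
    "sbp_maxima",          "sbp",     "gt",        sbp_high,
    "dbp_minima",          "dbp",     "le",        dbp_low,
    "dbp_maxima",          "dbp",     "gt",        dbp_high,
    "low_oxygen_saturation", "spo2",  "lt",        spo2_low,
    "low_heart_rate",      "hr",      "le",        hr_low
  )
}

alert_predicate <- function(value, comparator, threshold) {
  switch(comparator,
         le = value <= threshold,
         lt = value < threshold,
         ge = value >= threshold,
         gt = value > threshold,
         abort(paste0("unknown comparator '", comparator,
                      "'; use le, lt, ge or gt")))
}

#' Evaluate alert rules over vital records
#'
#' Applies each rule's predicate to every record of the matching
#' variable; a record matching several rules emits one event per matched
#' rule. Records are expected to be viability-filtered first, so alerts
#' flag clinically notable values rather than entry errors.
#'
#' @param records Vital records with `volunteer_id`, `timestamp`,
#'   `variable`, `value`.
#' @param rules A rules tibble as from [alert_rules()].
#' @return A tibble of alert events: `volunteer_id`, `timestamp`,
#'   `variable`, `value`, `label`.
#' @examples
#' rec <- tibble::tibble(volunteer_id = "V001",
#'                       timestamp = as.POSIXct("2022-03-01 10:00",
#'                                              tz = "UTC"),
#'                       variable = "spo2", value = 87.5)
#' evaluate_alerts(rec)
#' @export
evaluate_alerts <- function(records, rules = alert_rules()) {
  check_columns(records, c("volunteer_id", "timestamp", "variable", "value"),
                "`records`")
  check_columns(rules, c("label", "variable", "comparator", "threshold"),
                "`rules`")
  if (anyDuplicated(rules$label)) abort("rule labels must be unique")
  bad <- setdiff(unique(rules$variable), VITAL_VARIABLES)
  if (length(bad) > 0) {
    abort(paste0("alert rule(s) reference unknown variable(s): ",
                 paste(bad, collapse = ", ")))
  }
  purrr::pmap_dfr(rules, function(label, variable, comparator, threshold) {
    sub <- records[records$variable == variable, , drop = FALSE]
    hit <- alert_predicate(sub$value, comparator, threshold)
    tibble::tibble(volunteer_id = sub$volunteer_id[hit],
                   timestamp = sub$timestamp[hit],
                   variable = variable, value = sub$value[hit],
                   label = label)
  })
}

#' Tally alert events per rule
#'
#' Per rule: number of events, percentage of all events, number of
#' distinct volunteers with at least one event and (when the cohort size
#' is known) their percentage of the cohort. Rules with no events are
#' reported with zeros.
#'
#' @param events Alert events from [evaluate_alerts()].
#' @param rules The rules tibble the events were generated under.
#' @param n_volunteers Optional cohort size for volunteer percentages.
#' @return A tibble `label`, `n_events`, `pct_events`, `n_volunteers`,
#'   `pct_volunteers`, with attributes `total_events` and
#'   `total_volunteers`.
#' @export
alert_report <- function(events, rules = alert_rules(), n_volunteers = NULL) {
  check_columns(rules, "label", "`rules`")
  total <- nrow(events)
  per_rule <- tibble::tibble(label = rules$label) |>
    dplyr::left_join(
      events |>
        dplyr::group_by(.data$label) |>
        dplyr::summarise(n_events = dplyr::n(),
                         n_vol = dplyr::n_distinct(.data$volunteer_id),
                         .groups = "drop"),
      by = "label"
    ) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      n_vol = dplyr::coalesce(.data$n_vol, 0L),
      pct_events = if (total > 0) 100 * .data$n_events / total else 0,
      pct_volunteers = if (!is.null(n_volunteers)) {
        100 * .data$n_vol / n_volunteers
      } else NA_real_
    ) |>
    dplyr::select("label", "n_events", "pct_events",
                  n_volunteers = "n_vol", "pct_volunteers")
  attr(per_rule, "total_events") <- total
  attr(per_rule, "total_volunteers") <-
    if (total > 0) dplyr::n_distinct(events$volunteer_id) else 0L
  per_rule
}
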