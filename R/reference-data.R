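REFERENCE_TABLES <- c("sleep_sessions", "loa_published", "recruitment_funnel",
                      "enrollment_weeks", "followup_weeks", "record_types",
                      "alert_counts", "sync_bins")

#' Reference tables from a published telemonitoring validation cohort
#'
#' Small plain-text tables reproducing the printed summary statistics of
#' an 80-volunteer smartwatch telemonitoring validation study, shipped so
#' that the package's accounting functions can be verified against
#' published numbers:
#'
#' * `"sleep_sessions"` — per-volunteer, per-device sleep report times
#'   and stage totals for the eight polysomnography nights.
#' * `"loa_published"` — reported limits-of-agreement summaries (overall
#'   and per group).
#' * `"recruitment_funnel"`, `"enrollment_weeks"`, `"followup_weeks"` —
#'   cohort accounting counts.
#' * `"record_types"` — record counts by data type.
#' * `"alert_counts"` — alert events and affected volunteers per rule
#'   (plus the reported overall total).
#' * `"sync_bins"` — synchronization-delay bin counts for the continuous
#'   heart-rate stream.
#'
#' @param name One of the table names above.
#' @return A tibble.
#' @examples
#' reference_table("sync_bins")
#' @export
reference_table <- function(name) {
  name <- match.arg(name, REFERENCE_TABLES)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "wearagree", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
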