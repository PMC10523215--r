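#' Run the full telemonitoring analysis pipeline
#'
#' Orchestrates the end-to-end analysis under one configuration: cohort
#' and record generation (or ingestion of a supplied record table),
#' viability filtering, triplicate consolidation and pairing, the
#' repeated-measures limits-of-agreement block (limits, error bands,
#' error trend, correlation, per-group limits), group comparisons of
#' per-volunteer means, the weekday-filtered hourly heart-rate profile
#' analysis, paired sleep-session summaries, alert evaluation,
#' synchronization-delay accounting and the record tally. Reruns with
#' the same configuration produce identical bundles; the manifest
#' records the configuration hash, seed, package version and all row
#' counts and exclusion tallies needed to audit a run.
#'
#' @param config A [sim_config()] object.
#' @param manual_records Optional tibble (or CSV path) of manual vital
#'   records to analyse instead of simulated ones; requires
#'   `simulate = FALSE` callers to supply it.
#' @param simulate Generate the input streams from `config` (default).
#'   If `FALSE`, `manual_records` must be supplied; the continuous,
#'   sleep and synchronization stages are then skipped unless their
#'   inputs are part of the supplied data.
#' @param n_sleep_sessions Number of paired sleep sessions to simulate.
#' @param sync_sample Continuous records to carry into the
#'   synchronization-delay accounting (kept moderate by default since
#'   the delay histogram stabilizes quickly).
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV and the manifest as JSON.
#' @return A list of class `wear_bundle` with the result tables and a
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), manual_records = NULL,
                         simulate = is.null(manual_records),
                         n_sleep_sessions = 4L, sync_sample = 20000L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "wear_config"))
  if (!simulate && is.null(manual_records)) {
    abort("either supply `manual_records` or set `simulate = TRUE`")
  }
  if (is.character(manual_records)) {
    manual_records <- read_vital_records(manual_records)
  }

  roster <- sim_cohort(config)
  if (simulate) {
    manual_records <- sim_paired_visits(roster, config)
  }
  check_columns(manual_records,
                c("volunteer_id", "timestamp", "variable", "value", "device"),
                "`manual_records`")

  viable <- filter_viable(manual_records)
  consolidated <- consolidate_triplicates(viable)
  pairs <- build_daily_pairs(consolidated)

  loa <- loa_repeated(pairs)
  bands <- band_fractions(pairs)
  trend <- fit_error_trend(pairs)
  corr <- pair_correlation(pairs)
  by_group <- if (nrow(roster) > 0) loa_by_group(pairs, roster) else NULL
  means <- volunteer_means(pairs, roster = if (nrow(roster)) roster)
  comparison <- if (nrow(roster) &&
                    all(table(roster$group) >= 2)) compare_groups(means)

  continuous <- profiles <- manova <- curves <- sync_hist <- NULL
  if (simulate) {
    continuous <- sim_continuous_hr(roster, config) |> filter_weekdays()
    profiles <- hourly_profiles(continuous, roster)
    if (dplyr::n_distinct(profiles$volunteer_id) >=
        length(unique(profiles$hour)) + 2) {
      manova <- profile_manova(profiles)
    }
    curves <- group_hourly_curves(profiles)
    idx <- seq_len(min(sync_sample, nrow(continuous)))
    sync_hist <- bin_delays(sim_sync_delays(continuous[idx, ], config))
  }

  sleep <- NULL
  if (simulate && n_sleep_sessions > 0) {
    sessions <- purrr::map(seq_len(n_sleep_sessions), function(i) {
      pair <- sim_hypnogram_pair(config, session_id = sprintf("S%02d", i),
                                 index = i)
      summarize_sleep_session(pair$gold, pair$watch)
    })
    sleep <- list(
      summaries = purrr::map_dfr(sessions, "summaries"),
      comparisons = purrr::map_dfr(seq_along(sessions), function(i) {
        dplyr::mutate(sessions[[i]]$comparison,
                      session_id = sprintf("S%02d", i), .before = 1)
      })
    )
  }

  alerts <- evaluate_alerts(viable)
  alert_tally <- alert_report(alerts, n_volunteers = max(nrow(roster), 1))

  record_types <- dplyr::bind_rows(
    dplyr::transmute(manual_records,
                     type = paste0("manual_", .data$variable)),
    if (!is.null(continuous)) tibble::tibble(
      type = rep("continuous_hr", nrow(continuous)))
  ) |> record_tally()

  tally <- exclusion_tally(viable)
  manifest <- list(
    package = "wearagree",
    version = as.character(utils::packageVersion("wearagree")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    rows = list(
      manual_in = nrow(manual_records),
      manual_kept = nrow(viable),
      manual_excluded = sum(tally$excluded),
      triplicates_dropped = attr(consolidated, "dropped_incomplete"),
      pairs = nrow(pairs),
      continuous = if (is.null(continuous)) 0L else nrow(continuous),
      alerts = nrow(alerts)
    ),
    exclusion_tally = tally
  )
  stopifnot(manifest$rows$manual_in ==
              manifest$rows$manual_kept + manifest$rows$manual_excluded)

  bundle <- structure(
    list(roster = roster, pairs = pairs, consolidated = consolidated,
         loa = loa, bands = bands, trend = trend, correlation = corr,
         loa_by_group = by_group, volunteer_means = means,
         group_comparison = comparison, profiles = profiles,
         profile_tests = manova, hourly_curves = curves,
         sleep = sleep, alerts = alerts, alert_tally = alert_tally,
         sync = sync_hist, record_tally = record_types,
         manifest = manifest),
    class = "wear_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.wear_bundle <- function(x, ...) {
  cat("<wear_bundle> seed", x$manifest$seed, "|", x$manifest$rows$pairs,
      "daily pairs |", x$manifest$rows$continuous, "continuous records\n")
  invisible(x)
}

# write every tabular artifact of a bundle as CSV plus a JSON manifest
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  emit(bundle$roster, "roster")
  emit(bundle$pairs, "pairs")
  emit(bundle$consolidated, "consolidated")
  emit(tidy(bundle$loa), "loa_summary")
  emit(bundle$bands, "band_fractions")
  emit(tidy(bundle$trend), "error_trend")
  emit(bundle$correlation, "correlation")
  emit(bundle$loa_by_group, "loa_by_group")
  emit(bundle$volunteer_means, "volunteer_means")
  emit(bundle$group_comparison, "group_comparison")
  emit(bundle$hourly_curves, "hourly_curves")
  if (!is.null(bundle$profile_tests)) {
    emit(tidy(bundle$profile_tests), "profile_tests")
  }
  if (!is.null(bundle$sleep)) {
    emit(bundle$sleep$summaries, "sleep_summaries")
    emit(bundle$sleep$comparisons, "sleep_comparisons")
  }
  emit(bundle$alerts, "alerts")
  emit(bundle$alert_tally, "alert_tally")
  emit(bundle$sync, "sync_histogram")
  emit(bundle$record_tally, "record_tally")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
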