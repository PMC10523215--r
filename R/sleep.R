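GOLD_STAGES <- c("awake", "N1", "N2", "N3", "REM")
WATCH_STAGES <- c("awake", "light", "deep", "REM")

# collapse consecutive same-stage intervals into one
merge_stage_runs <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  run <- cumsum(c(TRUE, iv$stage[-1] != iv$stage[-nrow(iv)]))
  iv |>
    dplyr::group_by(run_id = run) |>
    dplyr::summarise(
      session_id = dplyr::first(.data$session_id),
      device = dplyr::first(.data$device),
      start = min(.data$start), end = max(.data$end),
      stage = dplyr::first(.data$stage), .groups = "drop"
    ) |>
    dplyr::select(!"run_id")
}

#' Map a five-stage epoch hypnogram onto the four watch stages
#'
#' Polysomnography scores 30-second epochs over `awake`, `N1`, `N2`, `N3`
#' and `REM`; consumer wearables report `awake`, `light`, `deep` and
#' `REM`. Following the standard harmonization, `N1` and `N2` map to
#' `light` and `N3` to `deep`; `awake` and `REM` are unchanged. Adjacent
#' epochs of the same mapped stage are merged into intervals, so the
#' total recorded duration is preserved exactly.
#'
#' @param epochs An epoch tibble with columns `session_id`, `device`,
#'   `start` (epoch start time, 30-s grid), `stage`.
#' @return An interval tibble with columns `session_id`, `device`,
#'   `start`, `end`, `stage` (four-stage vocabulary).
#' @export
map_stages <- function(epochs) {
  check_columns(epochs, c("session_id", "device", "start", "stage"),
                "epoch hypnogram")
  bad <- setdiff(unique(epochs$stage), GOLD_STAGES)
  if (length(bad) > 0) {
    abort(paste0("unknown sleep stage label(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(epochs) == 0) {
    return(tibble::tibble(session_id = character(), device = character(),
                          start = as_wall_clock(character()),
                          end = as_wall_clock(character()),
                          stage = character()))
  }
  epochs <- dplyr::arrange(epochs, .data$start)
  iv <- dplyr::mutate(
    epochs,
    end = .data$start + 30,
    stage = dplyr::recode(.data$stage, N1 = "light", N2 = "light",
                          N3 = "deep")
  )
  merge_stage_runs(dplyr::select(iv, "session_id", "device", "start", "end",
                                 "stage"))
}

#' Determine the time-in-bed window for each device
#'
#' The gold-standard report delimits time in bed (TIB) directly: it starts
#' when the volunteer lies down and ends when the report ends. The watch
#' does not record lights-off, so its TIB starts at the gold-standard
#' start and ends at the start of the last `awake` interval the watch
#' recorded (the moment the watch considered the wearer fully awake).
#'
#' @param gold Gold hypnogram: either an epoch tibble (column `start`,
#'   30-s epochs) or an interval tibble (`start`, `end`).
#' @param watch Watch interval tibble (four-stage).
#' @return A tibble with one row per device: `session_id`, `device`,
#'   `tib_start`, `tib_end`, `tib_s`.
#' @export
align_tib <- function(gold, watch) {
  check_columns(gold, c("session_id", "start"), "gold hypnogram")
  check_columns(watch, c("session_id", "start", "end", "stage"),
                "watch hypnogram")
  gold_start <- min(gold$start)
  gold_end <- if ("end" %in% names(gold)) max(gold$end) else max(gold$start) + 30
  awake <- watch$start[watch$stage == "awake"]
  if (length(awake) == 0) {
    abort("watch record has no awake interval; its time-in-bed end is undefined")
  }
  watch_end <- max(awake)
  tibble::tibble(
    session_id = rep(gold$session_id[1], 2),
    device = c("gold", "watch"),
    tib_start = rep(gold_start, 2),
    tib_end = c(gold_end, watch_end),
    tib_s = as.numeric(c(gold_end, watch_end)) -
      as.numeric(rep(gold_start, 2))
  )
}

#' Sleep-architecture metrics for one device record
#'
#' Computes the standard hypnogram summary within a time-in-bed window:
#' sleep latency (TIB start to the first sleep stage), total sleep time
#' (TST, summed light + deep + REM within TIB, intervals truncated at the
#' TIB end), sleep efficiency (SE = 100 * TST / TIB), wake after sleep
#' onset (WASO, awake time recorded between sleep onset and TIB end), and
#' per-stage totals. The reported `awake_s` is latency + WASO; awake time
#' before sleep onset counts toward latency, not WASO.
#'
#' @param intervals Four-stage interval tibble for one session/device.
#' @param tib_start,tib_end Time-in-bed bounds (from [align_tib()]).
#' @return A one-row tibble: `session_id`, `device`, `tib_s`, `latency_s`,
#'   `tst_s`, `se`, `waso_s`, `awake_s`, `light_s`, `deep_s`, `rem_s`,
#'   `no_sleep`.
#' @export
sleep_summary <- function(intervals, tib_start, tib_end) {
  check_columns(intervals, c("session_id", "device", "start", "end", "stage"),
                "hypnogram intervals")
  bad <- setdiff(unique(intervals$stage), WATCH_STAGES)
  if (length(bad) > 0) {
    abort(paste0("expected four-stage record; unknown stage(s): ",
                 paste(bad, collapse = ", ")))
  }
  tib_s <- as.numeric(tib_end) - as.numeric(tib_start)
  iv <- intervals |>
    dplyr::mutate(start = pmax(.data$start, tib_start),
                  end = pmin(.data$end, tib_end)) |>
    dplyr::filter(as.numeric(.data$end) > as.numeric(.data$start))

  sleep_iv <- iv[iv$stage != "awake", ]
  no_sleep <- nrow(sleep_iv) == 0
  if (no_sleep) {
    warn("record contains no sleep stage within TIB; latency undefined")
    first_sleep <- as_wall_clock(NA_character_)
    latency <- NA_real_
    waso <- 0
  } else {
    first_sleep <- min(sleep_iv$start)
    latency <- as.numeric(first_sleep) - as.numeric(tib_start)
    awake_iv <- iv[iv$stage == "awake", ]
    waso <- sum(pmax(
      as.numeric(pmin(awake_iv$end, tib_end)) -
        as.numeric(pmax(awake_iv$start, first_sleep)), 0))
  }
  dur <- function(stage) {
    sum(as.numeric(iv$end[iv$stage == stage]) -
          as.numeric(iv$start[iv$stage == stage]))
  }
  tst <- dur("light") + dur("deep") + dur("REM")
  tibble::tibble(
    session_id = intervals$session_id[1],
    device = intervals$device[1],
    tib_start = tib_start, tib_end = tib_end, tib_s = tib_s,
    first_sleep = first_sleep,
    latency_s = latency, tst_s = tst,
    se = 100 * tst / tib_s,
    waso_s = waso,
    awake_s = (if (no_sleep) 0 else latency) + waso,
    light_s = dur("light"), deep_s = dur("deep"), rem_s = dur("REM"),
    no_sleep = no_sleep
  )
}

#' Compare the two devices' sleep summaries for one session
#'
#' Watch-minus-gold deltas for the headline metrics and stage totals.
#' Descriptive only: with a handful of paired nights, no test statistic
#' is meaningful, so device concordance is assessed qualitatively.
#'
#' @param gold,watch One-row summaries from [sleep_summary()] for the same
#'   session.
#' @return A tibble with columns `metric`, `gold`, `watch`, `delta`.
#' @export
compare_sleep <- function(gold, watch) {
  if (gold$session_id[1] != watch$session_id[1]) {
    abort("summaries come from different sessions")
  }
  metrics <- c("tib_s", "latency_s", "tst_s", "se", "waso_s",
               "awake_s", "light_s", "deep_s", "rem_s")
  tibble::tibble(
    metric = metrics,
    gold = vapply(metrics, function(m) gold[[m]][1], numeric(1)),
    watch = vapply(metrics, function(m) watch[[m]][1], numeric(1))
  ) |>
    dplyr::mutate(delta = .data$watch - .data$gold)
}

#' Summarize one simulated or ingested paired sleep session
#'
#' Convenience wrapper: maps the gold epochs to the four-stage vocabulary,
#' aligns the time-in-bed windows, summarizes both devices and computes
#' the per-metric deltas.
#'
#' @param gold_epochs Gold five-stage epoch tibble.
#' @param watch_intervals Watch four-stage interval tibble.
#' @return A list with `tib`, `summaries` (two rows) and `comparison`.
#' @export
summarize_sleep_session <- function(gold_epochs, watch_intervals) {
  gold_iv <- map_stages(gold_epochs)
  tib <- align_tib(gold_epochs, watch_intervals)
  gs <- sleep_summary(gold_iv, tib$tib_start[1], tib$tib_end[tib$device == "gold"])
  ws <- sleep_summary(watch_intervals, tib$tib_start[1],
                      tib$tib_end[tib$device == "watch"])
  list(tib = tib, summaries = dplyr::bind_rows(gs, ws),
       comparison = compare_sleep(gs, ws))
}

#' Recompute sleep metrics from reported session times
#'
#' Given per-session reported time-in-bed bounds, first-sleep time and
#' total sleep time (as printed in device sleep reports), recomputes TIB,
#' sleep latency and sleep efficiency from first principles. Used to
#' verify that published summary tables are internally consistent.
#'
#' @param sessions A data frame with columns `tib_begin`, `tib_end`,
#'   `first_sleep` (date-times or ISO strings) and `tst` (`H:MM:SS`).
#' @return The input with `tib_s`, `tib`, `latency_s`, `latency`, `se`
#'   (percent, 2 decimals) appended.
#' @export
sleep_reference_metrics <- function(sessions) {
  check_columns(sessions, c("tib_begin", "tib_end", "first_sleep", "tst"),
                "sleep sessions")
  sessions |>
    dplyr::mutate(
      tib_s = as.numeric(as_wall_clock(.data$tib_end)) -
        as.numeric(as_wall_clock(.data$tib_begin)),
      tib = format_hms(.data$tib_s),
      latency_s = as.numeric(as_wall_clock(.data$first_sleep)) -
        as.numeric(as_wall_clock(.data$tib_begin)),
      latency = format_hms(.data$latency_s),
      se = round_half_up(100 * parse_hms(.data$tst) / .data$tib_s, 2)
    )
}
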