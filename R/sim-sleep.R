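#' Simulate a paired polysomnography / smartwatch sleep session
#'
#' Builds one night as the gold-standard device records it — a 30-second
#' epoch hypnogram over `awake`, `N1`, `N2`, `N3`, `REM` beginning at
#' lights-off, with an initial latency period, sleep cycles of light,
#' deep and REM sleep, occasional brief awakenings, and a final awake
#' period — and derives the smartwatch record from it: stages mapped to
#' `awake`/`light`/`deep`/`REM`, the record starting at the first detected
#' sleep stage, brief awakenings (shorter than the configured threshold)
#' missed with probability `miss_prob` and merged into surrounding sleep,
#' stage boundaries jittered and reported on the watch's coarser time
#' resolution, and the final awakening detected with a lag (the watch
#' needs a longer period of activity to consider the wearer fully awake).
#'
#' @param config A [sim_config()] object; see the `sleep` block.
#' @param session_id Identifier stamped on both records.
#' @param index Session index; sessions with different indices are
#'   independent but each is reproducible under the configured seed.
#' @return A list with `gold` (epoch tibble: `session_id`, `device`,
#'   `start`, `stage`), `watch` (interval tibble: `session_id`, `device`,
#'   `start`, `end`, `stage`), and the session `start`/`end` times.
#' @examples
#' pair <- sim_hypnogram_pair(sim_config(seed = 3))
#' head(pair$gold)
#' @export
sim_hypnogram_pair <- function(config, session_id = "S1", index = 1L) {
  stopifnot(inherits(config, "wear_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config, "sleep") + as.integer(index))
  sl <- config$sleep

  # dwell draws in whole 30-s epochs (at least one)
  dwell <- function(mean_min) {
    max(1L, as.integer(round(rgamma(1, shape = 4, scale = mean_min / 4) * 2)))
  }

  stages <- character(0)
  add <- function(stage, n) c(stages, rep(stage, n))
  latency_min <- rlnorm(1, log(sl$latency_mean_min) - 0.125, 0.5)
  stages <- add("awake", max(1L, as.integer(round(latency_min * 2))))
  for (cycle in seq_len(sl$n_cycles)) {
    stages <- add("N1", max(1L, dwell(sl$light_mean_min * 0.2)))
    stages <- add("N2", dwell(sl$light_mean_min * 0.8))
    stages <- add("N3", dwell(sl$deep_mean_min))
    stages <- add("N2", dwell(sl$light_mean_min * 0.4))
    stages <- add("REM", dwell(sl$rem_mean_min))
    if (runif(1) < sl$awakening_prob) {
      stages <- add("awake", dwell(sl$awakening_mean_min))
    }
  }
  stages <- add("awake", max(1L, as.integer(round(sl$final_awake_min * 2))))

  start <- as_wall_clock(config$start_date) +
    round((sl$start_hour + rnorm(1, 0, sl$start_jitter_h)) * 3600)
  gold <- tibble::tibble(
    session_id = session_id, device = "gold",
    start = start + 30 * (seq_along(stages) - 1),
    stage = stages
  )

  watch <- derive_watch_record(gold, sl, session_id)
  list(gold = gold, watch = watch, start = start,
       end = start + 30 * length(stages))
}

# build the smartwatch interval record from a gold epoch hypnogram
derive_watch_record <- function(gold, sl, session_id) {
  iv <- map_stages(gold)
  iv$device <- "watch"
  iv$session_id <- session_id

  # watch starts recording at the first detected sleep stage
  first_sleep <- which(iv$stage != "awake")[1]
  if (is.na(first_sleep)) return(iv[0, ])
  iv <- iv[first_sleep:nrow(iv), ]

  # brief gold awakenings are missed and absorbed into the preceding sleep
  if (nrow(iv) > 2) {
    brief <- which(
      iv$stage == "awake" &
        as.numeric(iv$end) - as.numeric(iv$start) < sl$miss_threshold_min * 60
    )
    brief <- setdiff(brief, c(1L, nrow(iv)))
    brief <- brief[runif(length(brief)) < sl$miss_prob]
    if (length(brief) > 0) {
      iv$stage[brief] <- iv$stage[brief - 1]
      iv <- merge_stage_runs(iv)
    }
  }

  # the watch flags the final awakening late
  if (sl$end_lag_mean_min > 0 && nrow(iv) >= 2) {
    lag <- round(rgamma(1, shape = 2, scale = sl$end_lag_mean_min / 2) * 60)
    n <- nrow(iv)
    iv$end[n - 1] <- iv$end[n - 1] + lag
    iv$start[n] <- iv$start[n] + lag
    iv$end[n] <- iv$end[n] + lag
  }

  # boundary jitter on internal stage transitions, then watch resolution
  n <- nrow(iv)
  if (n >= 2) {
    bounds <- as.numeric(iv$end[-n])
    bounds <- bounds + round(rnorm(n - 1, 0, sl$jitter_sd_min * 60))
    lo <- as.numeric(iv$start[1])
    for (i in seq_along(bounds)) {
      bounds[i] <- max(bounds[i], lo + 30)
      lo <- bounds[i]
    }
    bounds <- pmin(bounds, as.numeric(iv$end[n]) - 30 * rev(seq_len(n - 1)))
    iv$end[-n] <- as_wall_clock(bounds)
    iv$start[-1] <- as_wall_clock(bounds)
  }
  res <- sl$watch_resolution_s
  iv$start <- as_wall_clock(round(as.numeric(iv$start) / res) * res)
  iv$end <- as_wall_clock(round(as.numeric(iv$end) / res) * res)
  iv <- iv[as.numeric(iv$end) > as.numeric(iv$start), ]
  merge_stage_runs(iv)
}
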