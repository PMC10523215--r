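#' Attach synthetic platform-ingestion timestamps to records
#'
#' Synchronization between the watch's companion app and the platform is
#' sporadic: most records arrive within a day, but a heavy tail trickles
#' in over days to weeks. Delays are drawn from a two-component lognormal
#' mixture (in hours): a fast component covering same-day synchronization
#' and a slow component for the multi-day tail. The defaults are
#' calibrated so that roughly two-thirds of records arrive within 24
#' hours and under 10% after a week. All delays are strictly positive.
#'
#' @param records A tibble of records with a `timestamp` column
#'   (acquisition time).
#' @param config A [sim_config()] object; see the `sync` block.
#' @return A tibble with `record_id`, `acquired`, `ingested`, `delay_s`.
#' @export
sim_sync_delays <- function(records, config) {
  stopifnot(inherits(config, "wear_config"))
  check_columns(records, "timestamp", "`records`")
  if (nrow(records) == 0) {
    abort("`records` must contain at least one record")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config, "sync"))
  sy <- config$sync
  n <- nrow(records)
  fast <- runif(n) < sy$weight
  delay_h <- ifelse(fast,
                    rlnorm(n, sy$meanlog_fast, sy$sdlog_fast),
                    rlnorm(n, sy$meanlog_slow, sy$sdlog_slow))
  tibble::tibble(
    record_id = seq_len(n),
    acquired = records$timestamp,
    ingested = records$timestamp + delay_h * 3600,
    delay_s = delay_h * 3600
  )
}
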