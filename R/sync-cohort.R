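SYNC_BIN_LABELS <- c("<1 h", "1-2 h", "3-6 h", "7-12 h", "13-24 h",
                     "1-2 d", "3-7 d", "8-14 d", ">14 d")
SYNC_BIN_EDGES_H <- c(0, 1, 2, 6, 12, 24, 48, 168, 336, Inf)

#' Histogram of synchronization delays
#'
#' Bins the delay between a record's acquisition and its availability on
#' the platform into the standard reporting bins. The printed bin labels
#' ("1-2 h" followed by "3-6 h") are resolved as contiguous half-open
#' intervals with upper-inclusive bounds — (1 h, 2 h], (2 h, 6 h], ... —
#' the only partition under which the accumulated percentages reach
#' 100%. A delay of exactly 14 days therefore bins to "8-14 d".
#' Percentages are reported to 2 decimals (half-up rounding, matching
#' report conventions); negative delays are rejected and counted in the
#' `n_rejected` attribute.
#'
#' @param sync_records A tibble with `acquired` and `ingested` timestamps
#'   (or a precomputed `delay_s` column).
#' @return A tibble `bin`, `n`, `pct`, `cum_pct` in bin order, with an
#'   `n_rejected` attribute.
#' @export
bin_delays <- function(sync_records) {
  if (!"delay_s" %in% names(sync_records)) {
    check_columns(sync_records, c("acquired", "ingested"), "`sync_records`")
    sync_records$delay_s <- as.numeric(sync_records$ingested) -
      as.numeric(sync_records$acquired)
  }
  neg <- sync_records$delay_s < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " record(s) with negative delay rejected"))
  }
  delay_h <- sync_records$delay_s[!neg] / 3600
  bins <- cut(delay_h, breaks = SYNC_BIN_EDGES_H, labels = SYNC_BIN_LABELS,
              right = TRUE, include.lowest = TRUE)
  counts <- tibble::tibble(bin = SYNC_BIN_LABELS,
                           n = as.integer(table(bins)[SYNC_BIN_LABELS]))
  out <- sync_histogram(counts)
  attr(out, "n_rejected") <- sum(neg)
  out
}

#' @rdname bin_delays
#' @param counts A tibble with `bin` (the standard labels, in order) and
#'   `n` per-bin counts; percentage and accumulated-percentage columns
#'   are recomputed from the counts.
#' @export
sync_histogram <- function(counts) {
  check_columns(counts, c("bin", "n"), "`counts`")
  if (!identical(as.character(counts$bin), SYNC_BIN_LABELS)) {
    abort(paste0("`counts$bin` must be exactly: ",
                 paste(SYNC_BIN_LABELS, collapse = ", ")))
  }
  total <- sum(counts$n)
  counts |>
    dplyr::mutate(
      pct = round_half_up(100 * .data$n / total, 2),
      cum_pct = round_half_up(100 * cumsum(.data$n) / total, 2)
    )
}

#' Cohort accounting tables
#'
#' Recomputes the three enrollment bookkeeping tables of a longitudinal
#' cohort from their raw counts.
#'
#' `recruitment_funnel()` takes the recruitment stages (first row = total
#' recruited) and reports each stage as a percentage of recruited (1
#' decimal). `active_users()` takes new enrollments and dropouts per
#' follow-up block and accumulates the active-user count, erroring if a
#' dropout would precede any enrollment. `followup_distribution()` takes
#' the binned follow-up durations and reports volunteer and day shares.
#'
#' @param funnel A tibble `stage`, `n`; the first row is the recruitment
#'   total.
#' @return Each function returns its input with recomputed percentage
#'   (and cumulative) columns; `cohort_tables()` bundles all three in a
#'   list.
#' @export
recruitment_funnel <- function(funnel) {
  check_columns(funnel, c("stage", "n"), "`funnel`")
  total <- funnel$n[1]
  dplyr::mutate(funnel, pct = round_half_up(100 * .data$n / total, 1))
}

#' @rdname recruitment_funnel
#' @param enrollment A tibble `block`, `new`, `dropouts` in chronological
#'   order.
#' @export
active_users <- function(enrollment) {
  check_columns(enrollment, c("block", "new", "dropouts"), "`enrollment`")
  cum_new <- cumsum(enrollment$new)
  cum_drop <- cumsum(enrollment$dropouts)
  if (any(cum_drop > cum_new)) {
    abort("dropout recorded before the corresponding enrollment")
  }
  dplyr::mutate(enrollment, active = cum_new - cum_drop)
}

#' @rdname recruitment_funnel
#' @param followup A tibble `bin`, `volunteers`, `days` (binned follow-up
#'   durations).
#' @export
followup_distribution <- function(followup) {
  check_columns(followup, c("bin", "volunteers", "days"), "`followup`")
  followup |>
    dplyr::mutate(
      pct_volunteers = round_half_up(
        100 * .data$volunteers / sum(.data$volunteers), 1),
      pct_days = round_half_up(100 * .data$days / sum(.data$days), 1)
    )
}

#' @rdname recruitment_funnel
#' @export
cohort_tables <- function(funnel, enrollment, followup) {
  list(funnel = recruitment_funnel(funnel),
       active = active_users(enrollment),
       followup = followup_distribution(followup))
}

#' Tally records by type
#'
#' Counts records per type and reports each type's share of the grand
#' total (2 decimals). Accepts either raw typed records (one row per
#' record) or a pre-aggregated table with an `n` column of counts.
#'
#' @param records A tibble with a `type` column and optionally `n`.
#' @return A tibble `type`, `n`, `pct`, with a `total` attribute.
#' @export
record_tally <- function(records) {
  check_columns(records, "type", "`records`")
  counts <- if ("n" %in% names(records)) {
    dplyr::select(records, "type", "n")
  } else {
    dplyr::count(records, .data$type)
  }
  total <- sum(counts$n)
  out <- dplyr::mutate(counts,
                       pct = round_half_up(100 * .data$n / total, 2))
  attr(out, "total") <- total
  out
}
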