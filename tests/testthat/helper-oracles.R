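# brute-force repeated-measures LoA oracle: explicit sums over the one-way
# ANOVA definition, written independently of loa_repeated()
loa_oracle <- function(d, volunteer) {
  ids <- unique(volunteer)
  n <- length(ids)
  N <- length(d)
  grand <- sum(d) / N
  ssb <- 0
  ssw <- 0
  sum_m2 <- 0
  for (id in ids) {
    di <- d[volunteer == id]
    mi <- length(di)
    ssb <- ssb + mi * (mean(di) - grand)^2
    ssw <- ssw + sum((di - mean(di))^2)
    sum_m2 <- sum_m2 + mi^2
  }
  msb <- ssb / (n - 1)
  msw <- if (N > n) ssw / (N - n) else 0
  m0 <- (N - sum_m2 / N) / (n - 1)
  s2b <- max(0, (msb - msw) / m0)
  sd_total <- sqrt(s2b + msw)
  list(bias = grand, msw = msw, msb = msb, m0 = m0, sd_total = sd_total,
       loa_low = grand - 1.96 * sd_total, loa_high = grand + 1.96 * sd_total)
}

# build a paired-measurement tibble from difference vectors
make_pairs <- function(volunteer, d, variable = "spo2", gold = 95) {
  tibble::tibble(
    volunteer_id = volunteer,
    date = as.Date("2022-03-01") + seq_along(d),
    variable = variable,
    gold_value = rep_len(gold, length(d)),
    watch_value = rep_len(gold, length(d)) + d,
    difference = d
  )
}

# epoch hypnogram from run-length (stage, minutes) pairs
make_epochs <- function(..., start = as.POSIXct("2022-08-10 22:00:00",
                                                tz = "UTC"),
                        session_id = "S1", device = "gold") {
  runs <- list(...)
  stages <- unlist(lapply(runs, function(r) rep(r[[1]], 2 * r[[2]])))
  tibble::tibble(session_id = session_id, device = device,
                 start = start + 30 * (seq_along(stages) - 1), stage = stages)
}
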