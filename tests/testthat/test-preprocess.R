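test_that("viability filter keeps exactly the biologically plausible range", {
  rec <- tibble::tibble(
    variable = c("spo2", "spo2", "spo2", "hr", "hr", "hr", "sbp", "dbp"),
    value = c(59.9, 60, 100.1, 301, 300, 20, 19.9, 150)
  )
  kept <- filter_viable(rec)
  expect_equal(kept$value, c(60, 300, 20, 150))
  tally <- exclusion_tally(kept)
  expect_equal(tally$excluded[tally$variable == "spo2"], 2L)
  expect_equal(tally$excluded[tally$variable == "hr"], 1L)
  expect_equal(tally$excluded[tally$variable == "sbp"], 1L)
  expect_equal(tally$excluded[tally$variable == "dbp"], 0L)

  empty <- filter_viable(rec[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(exclusion_tally(empty)$excluded), 0L)

  expect_error(filter_viable(tibble::tibble(variable = "pulse", value = 70)),
               "unknown variable")
})

test_that("weekday filter removes weekend continuous records only", {
  rec <- tibble::tibble(
    timestamp = as.POSIXct(c("2022-02-26 10:00", "2022-02-25 10:00",
                             "2022-02-26 10:00", "2022-02-27 10:00"),
                           tz = "UTC"),
    mode = c("continuous", "continuous", "manual", "continuous"),
    value = 1:4
  )
  out <- filter_weekdays(rec)
  # Saturday and Sunday continuous records dropped, manual Saturday kept
  expect_equal(out$value, c(2, 3))
})

test_that("tolerance-region rules reproduce hand-traced consolidations", {
  cases <- list(
    list(v = c(100, 100, 100), value = 100, label = "all_within"),
    list(v = c(90, 92, 105), value = 91, label = "pair_with_extreme"),
    list(v = c(100, 107, 114), value = 107, label = "middle_only"),
    list(v = c(50, 70, 90), value = 70, label = "none_within"),
    # upper-gap variant of the pair rule
    list(v = c(90, 104, 105), value = 104.5, label = "pair_with_extreme")
  )
  for (cs in cases) {
    out <- consolidate_triple(cs$v)
    expect_equal(out$value, cs$value)
    expect_equal(out$case_label, cs$label)
  }
  expect_error(consolidate_triple(c(1, 2)), "exactly three")
})

test_that("consolidation is permutation-invariant, scale-equivariant and bounded", {
  grid <- expand.grid(base = c(45, 60, 80, 100, 120),
                      g1 = c(0, 0.5, 2, 4.49, 4.5, 6, 11, 25),
                      g2 = c(0, 0.5, 2, 4.49, 4.5, 6, 11, 25))
  labels_seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    v <- c(grid$base[i], grid$base[i] + grid$g1[i],
           grid$base[i] + grid$g1[i] + grid$g2[i])
    ref <- consolidate_triple(v)
    labels_seen <- union(labels_seen, ref$case_label)
    # permutation invariance over all 6 orderings
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    for (p in perms) {
      out <- consolidate_triple(v[p])
      expect_identical(out, ref)
    }
    # scale equivariance (TR scales with the values); triples whose gap
    # sits exactly on the tolerance boundary are excluded, since the
    # strict comparison is not stable under floating-point rescaling
    s0 <- sort(v)
    tr0 <- 0.1 * s0[1]
    on_boundary <- any(abs(c(diff(s0), s0[3] - s0[1]) - tr0) < 1e-9)
    if (!on_boundary) {
      scaled <- consolidate_triple(2.7 * v)
      expect_equal(scaled$value, 2.7 * ref$value, tolerance = 1e-12)
      expect_equal(scaled$case_label, ref$case_label)
    }
    # output bounded by the extremes
    expect_gte(ref$value, min(v))
    expect_lte(ref$value, max(v))
    # the stated conditions, under the stated precedence, match exactly one
    s <- sort(v)
    tr <- 0.1 * s[1]
    fired <- c(
      all_within = s[3] - s[1] < tr,
      middle_only = !(s[3] - s[1] < tr) && (s[2] - s[1] < tr) &&
        (s[3] - s[2] < tr),
      pair_with_extreme = !(s[3] - s[1] < tr) &&
        xor(s[2] - s[1] < tr, s[3] - s[2] < tr),
      none_within = !(s[2] - s[1] < tr) && !(s[3] - s[2] < tr) &&
        !(s[3] - s[1] < tr)
    )
    expect_equal(sum(fired), 1L)
    expect_equal(names(which(fired)), ref$case_label)
  }
  expect_setequal(labels_seen, c("all_within", "middle_only",
                                 "pair_with_extreme", "none_within"))
})

test_that("triplicate groups without exactly three readings are dropped", {
  rec <- tibble::tibble(
    volunteer_id = c(rep("V1", 3), rep("V2", 2)),
    date = as.Date("2022-03-01"),
    variable = "hr", device = "watch",
    value = c(70, 71, 72, 80, 81)
  )
  expect_message(out <- consolidate_triplicates(rec), "without exactly 3")
  expect_equal(nrow(out), 1L)
  expect_equal(out$volunteer_id, "V1")
  expect_equal(out$value, 71)
  expect_equal(attr(out, "dropped_incomplete"), 1L)
})

test_that("daily pairing joins devices and signs the difference watch - gold", {
  cons <- tibble::tibble(
    volunteer_id = c("V1", "V1", "V1", "V2"),
    date = as.Date(c("2022-03-01", "2022-03-01", "2022-03-02", "2022-03-01")),
    variable = "spo2",
    device = c("watch", "gold", "watch", "gold"),
    value = c(95, 97, 96, 99)
  )
  pairs <- build_daily_pairs(cons)
  # only the day observed by both devices pairs up
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$difference, -2)

  dup <- dplyr::bind_rows(cons, cons[1, ])
  expect_error(build_daily_pairs(dup), "duplicate")
})

test_that("vital record tables round-trip through the CSV dialect", {
  cfg <- sim_config(seed = 5, n_per_group = 2, days = 2)
  rec <- sim_paired_visits(sim_cohort(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vital_records(rec, path)
  back <- read_vital_records(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$value, rec$value)
  expect_equal(back$volunteer_id, rec$volunteer_id)
})
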