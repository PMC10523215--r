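test_that("volunteer means average days per device independently", {
  pairs <- tibble::tibble(
    volunteer_id = c("V1", "V1", "V2"),
    date = as.Date(c("2022-03-01", "2022-03-02", "2022-03-01")),
    variable = "spo2",
    watch_value = c(96, 98, 95),
    gold_value = c(97, 97, 99),
    difference = c(-1, 1, -4)
  )
  m <- volunteer_means(pairs)
  v1w <- m$mean_value[m$volunteer_id == "V1" & m$device == "watch"]
  v1g <- m$mean_value[m$volunteer_id == "V1" & m$device == "gold"]
  expect_equal(v1w, 97)
  expect_equal(v1g, 97)
  expect_equal(m$mean_value[m$volunteer_id == "V2" & m$device == "watch"], 95)
  expect_equal(m$n_days[m$volunteer_id == "V2"][1], 1L)
})

test_that("group comparison gives t = 0, p = 1 on identical groups", {
  means <- tibble::tibble(
    volunteer_id = sprintf("V%d", 1:8),
    group = rep(c("covid", "non_covid"), each = 4),
    variable = "hr", device = "watch",
    mean_value = rep(c(70, 72, 74, 76), 2)
  )
  out <- compare_groups(means)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$p_adj, 1)

  degen <- means[c(1, 5:8), ]
  expect_error(compare_groups(degen), "at least 2 volunteers")
})

test_that("holm adjustment spans the variables within each device", {
  set.seed(21)
  means <- tidyr::crossing(
    tibble::tibble(volunteer_id = sprintf("V%d", 1:10),
                   group = rep(c("covid", "non_covid"), each = 5)),
    variable = c("spo2", "hr", "sbp", "dbp"), device = c("watch", "gold")
  )
  means$mean_value <- rnorm(nrow(means), 90, 5)
  out <- compare_groups(means)
  for (dev in c("watch", "gold")) {
    sub <- out[out$device == dev, ]
    expect_equal(sort(sub$p_adj),
                 sort(p.adjust(sub$p_value, method = "holm")))
  }
})

test_that("hourly profiles apply the two-stage mean and drop partial coverage", {
  base <- as.POSIXct("2022-03-07 00:00:00", tz = "UTC")  # a Monday
  full_hours <- tibble::tibble(
    volunteer_id = "V1",
    timestamp = base + 3600 * (0:47),
    value = 70
  )
  # V2: hour 13 observed twice on day 1 (80, 90) and once on day 2 (90)
  v2 <- tibble::tibble(
    volunteer_id = "V2",
    timestamp = c(base + 3600 * (0:23),
                  base + 13 * 3600 + 600,
                  base + 86400 + 3600 * (0:23)),
    value = c(rep(60, 13), 80, rep(60, 10), 80, rep(60, 13), 90, rep(60, 10))
  )
  v3 <- tibble::tibble(volunteer_id = "V3", timestamp = base + 3600 * (8:20),
                       value = 65)
  roster <- tibble::tibble(volunteer_id = c("V1", "V2", "V3"),
                           group = c("covid", "non_covid", "covid"))
  expect_message(
    prof <- hourly_profiles(dplyr::bind_rows(full_hours, v2, v3), roster),
    "dropped"
  )
  expect_setequal(unique(prof$volunteer_id), c("V1", "V2"))
  expect_equal(attr(prof, "dropped"), "V3")
  expect_equal(prof$hr[prof$volunteer_id == "V1"], rep(70, 24))
  # day-1 hour 13 mean is (80 + 80) / 2 = 80, day 2 is 90 -> 85
  expect_equal(prof$hr[prof$volunteer_id == "V2" & prof$hour == 13], 85)
})

test_that("profile tests match hand formulas on two-hour toy profiles", {
  hrs <- c(70, 74, 72, 78, 71, 75, 69, 73,   # group a, 4 volunteers
           68, 75, 74, 77, 70, 76, 73, 74)   # group b, 4 volunteers
  profiles <- tibble::tibble(
    volunteer_id = rep(sprintf("V%d", 1:8), each = 2),
    group = rep(c("a", "b"), each = 8),
    hour = rep(0:1, 8),
    hr = hrs
  )
  fit <- profile_manova(profiles)
  tests <- tidy(fit)

  wide <- matrix(hrs, ncol = 2, byrow = TRUE)
  grp <- rep(c("a", "b"), each = 4)
  # level: one-way ANOVA on row means, explicit sums
  rm <- rowMeans(wide)
  ssb <- sum(tapply(rm, grp, function(x) length(x) * (mean(x) - mean(rm))^2))
  ssw <- sum((rm - ave(rm, grp))^2)
  f_level <- (ssb / 1) / (ssw / 6)
  expect_equal(tests$f[tests$hypothesis == "level"], f_level,
               tolerance = 1e-9)

  # flatness: one-sample Hotelling T2 on the single hour difference,
  # all volunteers pooled
  diff <- wide[, 2] - wide[, 1]
  s2 <- sum((diff - mean(diff))^2) / 7
  t2 <- 8 * mean(diff)^2 / s2
  row <- tests[tests$hypothesis == "flatness", ]
  expect_equal(row$statistic, t2, tolerance = 1e-9)
  expect_equal(row$f, t2 * (8 - 1) / ((8 - 1) * 1), tolerance = 1e-9)
  expect_equal(unname(c(row$df1, row$df2)), c(1, 7))

  # parallelism with p = 1 and two groups: exact F equals the pooled t^2
  tt <- t.test(diff ~ grp, var.equal = TRUE)
  row <- tests[tests$hypothesis == "parallelism", ]
  expect_equal(row$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("parallelism agrees with the stats::manova cross-check", {
  set.seed(22)
  n <- 14
  p_hours <- 5
  profiles <- tidyr::crossing(
    tibble::tibble(volunteer_id = sprintf("V%02d", 1:n),
                   group = rep(c("a", "b"), each = n / 2)),
    hour = 0:(p_hours - 1)
  )
  profiles$hr <- rnorm(nrow(profiles), 72, 4) +
    2 * profiles$hour * (profiles$group == "b")
  fit <- profile_manova(profiles)
  row <- tidy(fit)[tidy(fit)$hypothesis == "parallelism", ]

  wide <- matrix(profiles$hr[order(profiles$volunteer_id, profiles$hour)],
                 ncol = p_hours, byrow = TRUE)
  D <- wide[, -1] - wide[, -p_hours]
  grp <- factor(rep(c("a", "b"), each = n / 2))
  ref <- summary(stats::manova(D ~ grp), test = "Wilks")$stats
  expect_equal(row$statistic, ref[1, "Wilks"], tolerance = 1e-8)
  expect_equal(row$f, ref[1, "approx F"], tolerance = 1e-8)
  expect_equal(row$p_value, ref[1, "Pr(>F)"], tolerance = 1e-8)
})

test_that("level is shift-invariant and flatness ignores group labels", {
  set.seed(23)
  profiles <- tidyr::crossing(
    tibble::tibble(volunteer_id = sprintf("V%02d", 1:12),
                   group = rep(c("a", "b"), each = 6)),
    hour = 0:3
  )
  profiles$hr <- rnorm(nrow(profiles), 70, 3)
  f1 <- tidy(profile_manova(profiles))
  shifted <- dplyr::mutate(profiles, hr = hr + 11)
  f2 <- tidy(profile_manova(shifted))
  expect_equal(f1$f[f1$hypothesis == "level"], f2$f[f2$hypothesis == "level"],
               tolerance = 1e-9)
  relabeled <- dplyr::mutate(
    profiles, group = rep(rep(c("a", "b"), 6), each = 4))
  f3 <- tidy(profile_manova(relabeled))
  expect_equal(f1$statistic[f1$hypothesis == "flatness"],
               f3$statistic[f3$hypothesis == "flatness"], tolerance = 1e-6)
})

test_that("identical group profiles give lambda 1 and flat profiles T2 0", {
  one_group <- tidyr::crossing(volunteer_id = sprintf("V%d", 1:4), hour = 0:2)
  one_group$hr <- c(70, 75, 72, 71, 74, 70, 69, 76, 73, 72, 73, 71)
  profiles <- dplyr::bind_rows(
    dplyr::mutate(one_group, group = "a"),
    dplyr::mutate(one_group, volunteer_id = paste0(volunteer_id, "b"),
                  group = "b")
  )
  # identical profile sets in both groups: no interaction signal
  tests <- tidy(profile_manova(profiles))
  par <- tests[tests$hypothesis == "parallelism", ]
  expect_equal(par$statistic, 1, tolerance = 1e-12)
  expect_equal(par$f, 0, tolerance = 1e-12)
  expect_equal(par$p_value, 1, tolerance = 1e-12)

  flat <- profiles
  flat$hr <- 70 + as.numeric(factor(flat$volunteer_id)) %% 3
  t2 <- tidy(profile_manova(flat))
  expect_equal(t2$statistic[t2$hypothesis == "flatness"], 0,
               tolerance = 1e-12)

  # more contrasts than volunteers can support
  tiny <- tidyr::crossing(
    tibble::tibble(volunteer_id = sprintf("V%d", 1:4),
                   group = rep(c("a", "b"), each = 2)),
    hour = 0:3
  )
  tiny$hr <- rnorm(nrow(tiny), 70, 2)
  expect_error(profile_manova(tiny), "aggregate hours")
})
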