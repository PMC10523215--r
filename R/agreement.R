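#' Limits of agreement for repeated measures
#'
#' Bland-Altman limits of agreement when each volunteer contributes
#' multiple paired readings. For each variable, the watch-minus-gold
#' differences are decomposed by a fixed-effects one-way ANOVA across
#' volunteers: with `n` volunteers contributing `m_i` pairs each and
#' `N = sum(m_i)`,
#' \deqn{MSW = SSW / (N - n), \quad MSB = SSB / (n - 1),}
#' \deqn{m_0 = (N - \sum m_i^2 / N) / (n - 1),}
#' the between-volunteer variance component is
#' `sigma2_b = max(0, (MSB - MSW) / m0)` (negative estimates are
#' truncated to zero and flagged), the total difference variance is
#' `sigma2_d = sigma2_b + MSW`, and the 95% limits are
#' `bias +/- 1.96 * sd_total` around the grand mean difference. With one
#' pair per volunteer this reduces to the classic Bland-Altman limits
#' (ordinary SD of the differences). The multiplier 1.96 is used verbatim
#' (no small-sample t correction). `se_bias` is the standard error of the
#' grand mean under the fitted components.
#'
#' @param pairs Paired measurements from [build_daily_pairs()] (columns
#'   `volunteer_id`, `variable`, `difference`).
#' @return An object of class `loa_rm`; `tidy()` returns the per-variable
#'   summary tibble (`variable`, `n_pairs`, `n_volunteers`, `bias`,
#'   `se_bias`, `msw`, `msb`, `m0`, `sigma2_b`, `sd_total`, `loa_low`,
#'   `loa_high`, `truncated`), and `autoplot()` draws the Bland-Altman
#'   plot.
#' @references Bland & Altman style agreement for multiple observations
#'   per individual, one-way ANOVA formulation.
#' @export
loa_repeated <- function(pairs) {
  check_columns(pairs, c("volunteer_id", "variable", "difference"), "`pairs`")
  if (nrow(pairs) == 0) abort("`pairs` is empty")
  summary <- pairs |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(~ loa_one(.x$difference, .x$volunteer_id)) |>
    dplyr::ungroup()
  structure(list(summary = summary, pairs = pairs), class = "loa_rm")
}

# variance-component computation for one variable
loa_one <- function(d, volunteer) {
  m_i <- table(volunteer)
  n <- length(m_i)
  N <- length(d)
  if (n < 2) {
    abort("limits of agreement for repeated measures need at least 2 volunteers")
  }
  grand <- mean(d)
  means <- tapply(d, volunteer, mean)
  ssb <- sum(m_i * (means - grand)^2)
  ssw <- sum((d - means[as.character(volunteer)])^2)
  msb <- ssb / (n - 1)
  msw <- if (N > n) ssw / (N - n) else 0
  m0 <- (N - sum(m_i^2) / N) / (n - 1)
  sigma2_b_raw <- (msb - msw) / m0
  truncated <- sigma2_b_raw < 0
  sigma2_b <- max(0, sigma2_b_raw)
  sigma2_d <- sigma2_b + msw
  sd_total <- sqrt(sigma2_d)
  tibble::tibble(
    n_pairs = N, n_volunteers = n,
    bias = grand,
    se_bias = sqrt(sigma2_b / n + msw / N),
    msw = msw, msb = msb, m0 = m0, sigma2_b = sigma2_b,
    sd_total = sd_total,
    loa_low = grand - 1.96 * sd_total,
    loa_high = grand + 1.96 * sd_total,
    truncated = truncated
  )
}

#' @export
print.loa_rm <- function(x, ...) {
  cat("Repeated-measures limits of agreement (bias +/- 1.96 sd)\n")
  print(dplyr::select(x$summary, "variable", "n_pairs", "n_volunteers",
                      "bias", "sd_total", "loa_low", "loa_high"))
  if (any(x$summary$truncated)) {
    cat("note: negative between-volunteer variance truncated to 0 for:",
        paste(x$summary$variable[x$summary$truncated], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fraction of differences within error bands
#'
#' Segments the Bland-Altman plot into increasing intervals around zero
#' and reports, per variable, the percentage of pairs whose absolute
#' difference lies within each threshold (inclusive). Default thresholds
#' are 1/2/3% for SpO2, 5/10/15 mm Hg for the blood pressures and 1/2/3
#' bpm for heart rate.
#'
#' @inheritParams loa_repeated
#' @param thresholds Optional named list of positive ascending thresholds
#'   per variable, overriding the defaults.
#' @return A tibble `variable`, `threshold`, `n_within`, `fraction`
#'   (percent).
#' @export
band_fractions <- function(pairs, thresholds = NULL) {
  check_columns(pairs, c("variable", "difference"), "`pairs`")
  if (nrow(pairs) == 0) abort("`pairs` is empty")
  defaults <- list(spo2 = c(1, 2, 3), sbp = c(5, 10, 15), dbp = c(5, 10, 15),
                   hr = c(1, 2, 3))
  thresholds <- utils::modifyList(defaults, thresholds %||% list())
  purrr::map_dfr(sort(unique(pairs$variable)), function(v) {
    th <- thresholds[[v]]
    if (is.null(th) || any(th <= 0) || is.unsorted(th, strictly = TRUE)) {
      abort(paste0("thresholds for ", v, " must be positive and ascending"))
    }
    d <- pairs$difference[pairs$variable == v]
    tibble::tibble(
      variable = v, threshold = th,
      n_within = vapply(th, function(t) sum(abs(d) <= t), integer(1)),
      fraction = 100 * vapply(th, function(t) mean(abs(d) <= t), numeric(1))
    )
  })
}

#' Linear trend of the error against the true value
#'
#' Ordinary least squares of the watch-minus-gold difference on the
#' gold-standard ("true") value, per variable. The `center` is the
#' fitted zero-crossing `-intercept / slope`: the true value around
#' which the watch appears calibrated, from which its error grows
#' linearly.
#'
#' @inheritParams loa_repeated
#' @return An object of class `error_trend`; `tidy()` returns a tibble
#'   `variable`, `slope`, `intercept`, `center`, `n_pairs`.
#' @export
fit_error_trend <- function(pairs) {
  check_columns(pairs, c("variable", "gold_value", "difference"), "`pairs`")
  fits <- pairs |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_map(function(df, key) {
      if (length(unique(df$gold_value)) < 3) {
        abort(paste0("error trend for ", key$variable,
                     " needs at least 3 distinct gold values"))
      }
      fit <- lm(difference ~ gold_value, data = df)
      slope <- unname(coef(fit)[2])
      intercept <- unname(coef(fit)[1])
      list(variable = key$variable, fit = fit,
           row = tibble::tibble(
             variable = key$variable, slope = slope, intercept = intercept,
             center = if (slope != 0) -intercept / slope else NA_real_,
             n_pairs = nrow(df)
           ))
    })
  structure(list(summary = purrr::map_dfr(fits, "row"),
                 fits = setNames(purrr::map(fits, "fit"),
                                 purrr::map_chr(fits, "variable"))),
            class = "error_trend")
}

#' @export
print.error_trend <- function(x, ...) {
  cat("Linear error trend (difference ~ gold value)\n")
  print(x$summary)
  invisible(x)
}

#' Naive correlation between the devices
#'
#' Pearson correlation of the watch and gold readings per variable.
#' Reported for comparability with conventional method-comparison write-ups,
#' but flagged: repeated measurements on the same volunteer are not
#' independent, so this coefficient overstates the evidence and the
#' limits-of-agreement analysis is the primary tool.
#'
#' @inheritParams loa_repeated
#' @return A tibble `variable`, `r`, `n_pairs`, `dependent_pairs`
#'   (always `TRUE`, the caveat flag).
#' @export
pair_correlation <- function(pairs) {
  check_columns(pairs, c("variable", "watch_value", "gold_value"), "`pairs`")
  pairs |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) abort("correlation needs at least 3 pairs")
      if (sd(df$watch_value) == 0 || sd(df$gold_value) == 0) {
        abort("correlation undefined: zero variance on one device")
      }
      tibble::tibble(r = cor(df$watch_value, df$gold_value),
                     n_pairs = nrow(df), dependent_pairs = TRUE)
    }) |>
    dplyr::ungroup()
}

#' Limits of agreement per study group
#'
#' Applies [loa_repeated()] separately to each group's subset of pairs.
#' No test statistic is computed across groups — group limits are
#' compared qualitatively, on clinical rather than statistical grounds.
#' Groups with fewer than two volunteers are omitted with a warning.
#'
#' @inheritParams loa_repeated
#' @param roster A roster with `volunteer_id` and `group` columns covering
#'   every volunteer in `pairs`.
#' @return A tibble: the per-variable LoA summary with a leading `group`
#'   column.
#' @export
loa_by_group <- function(pairs, roster) {
  check_columns(roster, c("volunteer_id", "group"), "`roster`")
  unknown <- setdiff(unique(pairs$volunteer_id), roster$volunteer_id)
  if (length(unknown) > 0) {
    abort(paste0("volunteer(s) missing from roster: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    pairs, dplyr::select(roster, "volunteer_id", "group"),
    by = "volunteer_id"
  )
  purrr::map_dfr(sort(unique(joined$group)), function(g) {
    sub <- joined[joined$group == g, ]
    if (length(unique(sub$volunteer_id)) < 2) {
      warn(paste0("group '", g, "' has fewer than 2 volunteers; omitted"))
      return(NULL)
    }
    dplyr::mutate(loa_repeated(sub)$summary, group = g, .before = 1)
  })
}
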