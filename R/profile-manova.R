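#' MANOVA profile analysis of hourly heart-rate curves
#'
#' Tests the three classical profile-analysis hypotheses on the
#' volunteers' 24-hour heart-rate vectors:
#'
#' * **level** — do the groups differ in overall (baseline) heart rate?
#'   One-way ANOVA F on each volunteer's profile grand mean.
#' * **flatness** — does heart rate vary along the day at all? One-sample
#'   Hotelling T-squared on the 23 adjacent-hour differences with all
#'   volunteers pooled: `T2 = N * dbar' S^-1 dbar` with `S` the sample
#'   covariance of the differences, converted to F with
#'   `F = (N - p) / ((N - 1) p) * T2` on `(p, N - p)` degrees of
#'   freedom. Pooling over volunteers makes the test invariant to the
#'   group labelling.
#' * **parallelism** — does the shape of the daily curve differ between
#'   groups (the group-by-time interaction)? Wilks' Lambda for the group
#'   effect on the difference vectors,
#'   `Lambda = det(E) / det(E + H)`, with Rao's F approximation (exact
#'   for two groups).
#'
#' The successive-differences contrast (hour h+1 minus hour h) is used;
#' any full-rank contrast yields the same Lambda. Differences are
#' computed from profiles averaged per hour and across days, so the
#' autocorrelation of the raw stream is absorbed into the multivariate
#' covariance rather than modelled explicitly.
#'
#' @param profiles Long profiles from [hourly_profiles()]: columns
#'   `volunteer_id`, `group`, `hour`, `hr`, complete in hour per
#'   volunteer.
#' @param alpha Significance level used only for printing (default .05).
#' @return An object of class `profile_manova`. `tidy()` returns one row
#'   per hypothesis (`hypothesis`, `statistic_name`, `statistic`, `f`,
#'   `df1`, `df2`, `p_value`); `glance()` returns a one-row overview.
#' @export
profile_manova <- function(profiles, alpha = 0.05) {
  check_columns(profiles, c("volunteer_id", "group", "hour", "hr"),
                "`profiles`")
  wide <- profiles |>
    dplyr::arrange(.data$volunteer_id, .data$hour) |>
    tidyr::pivot_wider(id_cols = c("volunteer_id", "group"),
                       names_from = "hour", values_from = "hr")
  Y <- as.matrix(wide[, -(1:2)])
  if (anyNA(Y)) abort("profiles must be complete in hour for every volunteer")
  grp <- factor(wide$group)
  g <- nlevels(grp)
  N <- nrow(Y)
  p <- ncol(Y) - 1
  if (g < 2) abort("profile analysis needs at least 2 groups")
  if (any(table(grp) < 2)) abort("each group needs at least 2 volunteers")
  if (N - g - p + 1 < 1) {
    abort(paste0("too few volunteers (", N, ") for ", p,
                 " contrasts and ", g, " groups; aggregate hours into ",
                 "coarser bins before testing"))
  }

  # level: one-way ANOVA on profile grand means
  lvl_means <- rowMeans(Y)
  lvl <- anova(aov(lvl_means ~ grp))
  level <- tibble::tibble(
    hypothesis = "level", statistic_name = "F",
    statistic = lvl$`F value`[1], f = lvl$`F value`[1],
    df1 = lvl$Df[1], df2 = lvl$Df[2], p_value = lvl$`Pr(>F)`[1]
  )

  # successive-differences contrast
  D <- Y[, -1, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]
  split_rows <- split(seq_len(N), grp)
  S_pooled <- Reduce(`+`, lapply(split_rows, function(idx) {
    Dg <- D[idx, , drop = FALSE]
    crossprod(scale(Dg, center = TRUE, scale = FALSE))
  })) / (N - g)

  # flatness: one-sample Hotelling T2 on the difference vectors with all
  # volunteers pooled (covariance about the grand mean), so the test is
  # exactly invariant to the group labelling; identically flat profiles
  # give a zero mean vector, hence T2 = 0, without requiring an
  # invertible covariance
  dbar <- colMeans(D)
  S_all <- stats::cov(D)
  t2 <- if (all(abs(dbar) < 1e-12)) 0 else {
    N * drop(crossprod(dbar, solve(S_all, dbar)))
  }
  f_flat <- (N - p) / ((N - 1) * p) * t2
  flatness <- tibble::tibble(
    hypothesis = "flatness", statistic_name = "Hotelling T2",
    statistic = t2, f = f_flat, df1 = p, df2 = N - p,
    p_value = pf(f_flat, p, N - p, lower.tail = FALSE)
  )

  # parallelism: Wilks Lambda for the group effect on the differences
  E <- S_pooled * (N - g)
  grand <- colMeans(D)
  H <- Reduce(`+`, lapply(split_rows, function(idx) {
    mg <- colMeans(D[idx, , drop = FALSE])
    length(idx) * tcrossprod(mg - grand)
  }))
  lambda <- exp(determinant(E, logarithm = TRUE)$modulus -
                  determinant(E + H, logarithm = TRUE)$modulus)
  lambda <- as.numeric(lambda)
  nu_h <- g - 1
  nu_e <- N - g
  t_exp <- if (p^2 + nu_h^2 - 5 > 0) {
    sqrt((p^2 * nu_h^2 - 4) / (p^2 + nu_h^2 - 5))
  } else 1
  w <- nu_e + nu_h - (p + nu_h + 1) / 2
  df1 <- p * nu_h
  df2 <- w * t_exp - (p * nu_h - 2) / 2
  lam_t <- lambda^(1 / t_exp)
  f_par <- (1 - lam_t) / lam_t * df2 / df1
  parallel <- tibble::tibble(
    hypothesis = "parallelism", statistic_name = "Wilks Lambda",
    statistic = lambda, f = f_par, df1 = df1, df2 = df2,
    p_value = pf(f_par, df1, df2, lower.tail = FALSE)
  )

  structure(
    list(tests = dplyr::bind_rows(level, flatness, parallel),
         n = N, n_groups = g, p = p, alpha = alpha,
         group_sizes = table(grp), profiles = profiles),
    class = "profile_manova"
  )
}

#' @export
print.profile_manova <- function(x, ...) {
  cat("Profile analysis of hourly heart-rate curves (",
      x$n, " volunteers, ", x$p, " contrasts)\n", sep = "")
  print(x$tests)
  sig <- x$tests$hypothesis[x$tests$p_value < x$alpha]
  cat("rejected at alpha =", x$alpha, ":",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
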