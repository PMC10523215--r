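#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rnorm runif rlnorm rgamma sd var lm coef aov anova
#'   t.test p.adjust pf cor qnorm plnorm complete.cases setNames
#' @importFrom utils head
NULL

VITAL_VARIABLES <- c("spo2", "sbp", "dbp", "hr")

#' Parse and format clock durations
#'
#' Durations in sleep reports are conventionally printed as `H:MM:SS`.
#' `parse_hms()` converts such strings to seconds; `format_hms()` is the
#' inverse (hours are zero-padded to two digits).
#'
#' @param x For `parse_hms()`, a character vector like `"08:37:10"`; for
#'   `format_hms()`, a numeric vector of seconds.
#' @return A numeric vector of seconds, or a character vector.
#' @examples
#' parse_hms("08:37:10")
#' format_hms(31030)
#' @export
parse_hms <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3 || anyNA(suppressWarnings(as.numeric(p)))) {
      abort(paste0("cannot parse duration '", paste(p, collapse = ":"),
                   "'; expected H:MM:SS"))
    }
    sum(as.numeric(p) * c(3600, 60, 1))
  }, numeric(1))
}

#' @rdname parse_hms
#' @export
format_hms <- function(x) {
  x <- round(x)
  sprintf("%02d:%02d:%02d", x %/% 3600, (x %% 3600) %/% 60, x %% 60)
}

# round half away from zero at d decimals, the convention used in the
# printed report tables (base round() goes to even)
round_half_up <- function(x, d = 2) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}

# ISO weekday 1 (Mon) .. 7 (Sun); timestamps are local wall-clock
iso_weekday <- function(x) as.integer(format(x, "%u"))

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_variables <- function(x) {
  bad <- setdiff(unique(x), VITAL_VARIABLES)
  if (length(bad) > 0) {
    rows <- which(x %in% bad)
    abort(paste0("unknown variable code(s) ", paste(bad, collapse = ", "),
                 " (rows ", paste(head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) ", ..." else "", ")"))
  }
  invisible(x)
}

as_wall_clock <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}
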