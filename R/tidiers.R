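#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted agreement and profile objects
#'
#' `tidy()` returns the per-term summary tibble of a fit; `glance()`
#' returns a one-row overview.
#'
#' @param x A `loa_rm`, `error_trend` or `profile_manova` object.
#' @param ... Unused.
#' @return A tibble.
#' @name wearagree-tidiers
NULL

#' @rdname wearagree-tidiers
#' @method tidy loa_rm
#' @export
tidy.loa_rm <- function(x, ...) x$summary

#' @rdname wearagree-tidiers
#' @method glance loa_rm
#' @export
glance.loa_rm <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$summary),
    n_pairs = sum(x$summary$n_pairs),
    n_volunteers = max(x$summary$n_volunteers),
    any_truncated = any(x$summary$truncated)
  )
}

#' @rdname wearagree-tidiers
#' @method tidy error_trend
#' @export
tidy.error_trend <- function(x, ...) x$summary

#' @rdname wearagree-tidiers
#' @method glance error_trend
#' @export
glance.error_trend <- function(x, ...) {
  tibble::tibble(n_variables = nrow(x$summary),
                 n_pairs = sum(x$summary$n_pairs))
}

#' @rdname wearagree-tidiers
#' @method tidy profile_manova
#' @export
tidy.profile_manova <- function(x, ...) x$tests

#' @rdname wearagree-tidiers
#' @method glance profile_manova
#' @export
glance.profile_manova <- function(x, ...) {
  p <- setNames(x$tests$p_value, x$tests$hypothesis)
  tibble::tibble(
    n_volunteers = x$n, n_groups = x$n_groups, n_contrasts = x$p,
    p_level = p[["level"]], p_flatness = p[["flatness"]],
    p_parallelism = p[["parallelism"]]
  )
}
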