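#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth fit
#'
#' @param x a [fit_growth_rate()] result.
#' @param ... unused.
#' @return tibble with one row per estimated quantity (`growth_rate`,
#'   `doubling_time`) and its value.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("growth_rate", "doubling_time"),
    estimate = c(x$growth_rate, x$doubling_time),
    unit = c("1/h", "h")
  )
}

#' One-row summary of a growth fit
#'
#' @param x a [fit_growth_rate()] result.
#' @param ... unused.
#' @return one-row tibble with the rate, doubling time, window and fit
#'   quality.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    growth_rate = x$growth_rate,
    doubling_time = x$doubling_time,
    r_squared = x$r_squared,
    window_start = unname(x$window["start"]),
    window_end = unname(x$window["end"]),
    n_points = nrow(x$curve),
    low_confidence = x$low_confidence
  )
}

#' Tidy a positional-bias curve
#'
#' @param x a [fit_positional_bias()] result.
#' @param ... unused.
#' @return tibble with `dx` and the fitted log2 `offset`.
#' @method tidy bias_curve
#' @export
tidy.bias_curve <- function(x, ...) {
  tibble(dx = x$dx, offset = x$offset)
}

#' One-row summary of a positional-bias curve
#'
#' @param x a [fit_positional_bias()] result.
#' @param ... unused.
#' @return one-row tibble with the fitted amplitude (max minus min offset),
#'   dx range, number of pairs and span.
#' @method glance bias_curve
#' @export
glance.bias_curve <- function(x, ...) {
  tibble(
    amplitude = max(x$offset) - min(x$offset),
    dx_min = min(x$dx),
    dx_max = max(x$dx),
    n_pairs = nrow(x$pairs),
    span = x$span
  )
}
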