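# Window statistics from cumulative sums: slope and R^2 of y ~ x on every
# contiguous window of a given length, in O(1) per window.
window_stats <- function(x, y, starts, len) {
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  cxy <- c(0, cumsum(x * y))
  e <- starts + len - 1L
  sx <- cx[e + 1L] - cx[starts]
  sy <- cy[e + 1L] - cy[starts]
  sxx <- cx2[e + 1L] - cx2[starts] - sx^2 / len
  syy <- cy2[e + 1L] - cy2[starts] - sy^2 / len
  sxy <- cxy[e + 1L] - cxy[starts] - sx * sy / len
  slope <- sxy / sxx
  scale_y <- pmax(cy2[e + 1L] - cy2[starts], .Machine$double.eps)
  r2 <- ifelse(syy <= 1e-12 * scale_y, 0, sxy^2 / (sxx * syy))
  list(slope = slope, r2 = pmin(r2, 1))
}

#' Locate the log-linear portion of a growth curve
#'
#' Uses the easy-linear strategy standard for plate-reader growth curves
#' (Hall et al. 2014, Mol Biol Evol 31:232): score the slope of `log(OD)`
#' versus time in every `w_min`-point sliding window, find the window with
#' the maximal slope, and accept every window whose slope reaches at least
#' `quota` of that maximum. The reported window is the union of the
#' accepted windows, refit by least squares. Lag and
#' saturation points never enter: any small window touching them has a
#' visibly diluted slope, so on a noiseless three-phase curve the exact
#' exponential segment is recovered. `low_confidence` is set when the final
#' fit has R^2 below `r2_min` or when no window grows at all (maximal
#' slope <= 0, in which case the best-R^2 `w_min` window is returned).
#'
#' @param time time points, hours, strictly increasing.
#' @param log_od natural log of optical density at those times.
#' @param w_min minimum window length in points.
#' @param r2_min R^2 below which the final fit is flagged low-confidence.
#' @param quota fraction of the maximal sliding-window slope a window must
#'   reach to join the fitted run.
#' @param h sliding-window width in points; defaults to
#'   `max(w_min, ceiling(n/6))` so that resolution tracks sampling density.
#' @return list with `start`, `end` (indices), `slope`, `r_squared`,
#'   `low_confidence`.
#' @export
detect_linear_window <- function(time, log_od, w_min = 5, r2_min = 0.99,
                                 quota = 0.95, h = NULL) {
  n <- length(time)
  if (length(log_od) != n) {
    abort("`time` and `log_od` lengths differ", class = "gx_data_error")
  }
  if (n < w_min) {
    abort(paste0("need at least ", w_min, " points"), class = "gx_data_error")
  }
  if (any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing", class = "gx_data_error")
  }
  # sliding width: never below w_min, and wide enough on densely sampled
  # curves that single-window slope noise cannot dominate the maximum
  if (is.null(h)) h <- max(w_min, ceiling(n / 6))
  h <- as.integer(min(h, n))
  starts <- seq_len(n - h + 1L)
  st <- window_stats(time, log_od, starts, h)
  if (all(st$slope <= 0)) {
    best <- order(-st$r2, starts)[1]
    return(list(start = starts[best], end = starts[best] + h - 1L,
                slope = st$slope[best], r_squared = st$r2[best],
                low_confidence = TRUE))
  }
  imax <- which.max(st$slope)
  accepted <- which(st$slope >= quota * st$slope[imax])
  # union of all accepted windows: spans the exponential phase while lag
  # and saturation windows stay below the quota
  s <- starts[min(accepted)]
  e <- starts[max(accepted)] + h - 1L
  fit <- window_stats(time, log_od, s, e - s + 1L)
  list(start = s, end = e, slope = fit$slope, r_squared = fit$r2,
       low_confidence = fit$r2 < r2_min || fit$slope <= 0)
}

#' Fit the exponential growth rate of one OD curve
#'
#' Least-squares slope of `ln(OD)` versus time over the detected log-linear
#' window ([detect_linear_window()]); the doubling time is
#' `ln(2) / growth_rate`.
#'
#' @param curve tibble with columns `time_h` and `od` (and optionally
#'   `strain_id`, `condition`, carried through).
#' @param w_min,r2_min,quota window-detection parameters
#'   (see [detect_linear_window()]).
#' @param blank constant blank OD subtracted before the log transform.
#' @return object of class `growth_fit`: growth rate (1/h), doubling time
#'   (h), window indices, R^2 and a low-confidence flag; supports
#'   [tidy()], [glance()] and `autoplot()`.
#' @examples
#' tt <- seq(0, 8, by = 0.5)
#' fit <- fit_growth_rate(tibble::tibble(time_h = tt, od = 0.05 * 2^(tt / 2)))
#' glance(fit)  # growth_rate = log(2)/2, doubling_time = 2 h
#' @export
fit_growth_rate <- function(curve, w_min = 5, r2_min = 0.99, quota = 0.95,
                            blank = 0) {
  if (!all(c("time_h", "od") %in% names(curve))) {
    abort("`curve` needs columns time_h and od", class = "gx_data_error")
  }
  od <- curve$od - blank
  if (any(!is.finite(od)) || any(od <= 0)) {
    abort("OD values must be positive and finite (after blank subtraction)",
          class = "gx_data_error")
  }
  time <- curve$time_h
  win <- detect_linear_window(time, log(od), w_min = w_min,
                              r2_min = r2_min, quota = quota)
  if (!is.finite(win$slope) || win$slope <= 0) {
    abort("no window with positive growth found; culture is not growing",
          class = "gx_fit_error")
  }
  structure(
    list(growth_rate = win$slope,
         doubling_time = log(2) / win$slope,
         r_squared = win$r_squared,
         window = c(start = win$start, end = win$end),
         low_confidence = win$low_confidence,
         strain_id = if ("strain_id" %in% names(curve)) curve$strain_id[1]
                     else NA_character_,
         condition = if ("condition" %in% names(curve)) curve$condition[1]
                     else NA_character_,
         curve = as_tibble(curve[c("time_h", "od")])),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  cat(sprintf("  growth rate %.4f /h (doubling time %.2f h)\n",
              x$growth_rate, x$doubling_time))
  cat(sprintf("  window points %d..%d, R^2 = %.4f%s\n",
              x$window["start"], x$window["end"], x$r_squared,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Fit growth rates for every strain and condition in a curve table
#'
#' @param curves long tibble with `strain_id`, `condition`, `time_h`, `od`.
#' @param w_min,r2_min,quota,blank passed to [fit_growth_rate()].
#' @return tibble with one row per strain x condition: `growth_rate`,
#'   `doubling_time`, `r_squared`, `window_start`, `window_end`,
#'   `low_confidence`.
#' @export
fit_growth_rates <- function(curves, w_min = 5, r2_min = 0.99,
                             quota = 0.95, blank = 0) {
  if (!all(c("strain_id", "condition", "time_h", "od") %in% names(curves))) {
    abort("`curves` needs strain_id, condition, time_h, od",
          class = "gx_data_error")
  }
  curves %>%
    group_by(.data$strain_id, .data$condition) %>%
    dplyr::group_modify(function(d, key) {
      fit <- fit_growth_rate(d, w_min = w_min, r2_min = r2_min,
                             quota = quota, blank = blank)
      tibble(growth_rate = fit$growth_rate,
             doubling_time = fit$doubling_time,
             r_squared = fit$r_squared,
             window_start = unname(fit$window["start"]),
             window_end = unname(fit$window["end"]),
             low_confidence = fit$low_confidence)
    }) %>%
    ungroup()
}

#' Cohort growth-rate dispersion (coefficient of variation)
#'
#' Sample standard deviation (n - 1 denominator) of the rates divided by
#' their mean — the inter-strain dispersion statistic used to contrast
#' growth on glucose with growth on xylulose.
#'
#' @param rates numeric growth rates of >= 2 strains.
#' @return a single number, std/mean.
#' @export
cohort_dispersion <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2) {
    abort("need >= 2 rates", class = "gx_data_error")
  }
  m <- mean(rates)
  if (m == 0) abort("mean rate is zero", class = "gx_data_error")
  sd(rates) / m
}
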