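#' Plot a growth fit: log OD versus time with the fitted window
#'
#' @param object a [fit_growth_rate()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- mutate(object$curve,
              in_window = dplyr::row_number() >= object$window["start"] &
                dplyr::row_number() <= object$window["end"])
  win <- d[d$in_window, ]
  fitline <- tibble(
    time_h = range(win$time_h),
    log_od = mean(log(win$od)) +
      object$growth_rate * (range(win$time_h) - mean(win$time_h))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = log(.data$od))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window), size = 1.5) +
    ggplot2::geom_line(data = fitline,
                       ggplot2::aes(x = .data$time_h, y = .data$log_od),
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
                                            `FALSE` = "grey60"),
                                 name = "fitted window") +
    ggplot2::labs(
      x = "time (h)", y = "ln OD",
      title = sprintf("growth rate %.3f /h, doubling time %.2f h",
                      object$growth_rate, object$doubling_time)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a positional-bias fit: dy versus dx with the Lowess trend
#'
#' @param object a [fit_positional_bias()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bias_curve
#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.8) +
    ggplot2::geom_line(data = tidy(object),
                       ggplot2::aes(x = .data$dx, y = .data$offset),
                       colour = "#d95f02", linewidth = 0.8) +
    ggplot2::labs(x = "dx (bp to 3'-most probe)",
                  y = "dy (log2 ratio to P_last)",
                  title = "3'-positional probe bias") +
    ggplot2::theme_minimal()
}

#' Plot a group correlation scan
#'
#' @param object a [scan_groups()] result.
#' @param ... unused.
#' @return a ggplot: Pearson r per group, significant groups highlighted.
#' @method autoplot group_scan
#' @export
autoplot.group_scan <- function(object, ...) {
  d <- mutate(as_tibble(object),
              group = factor(.data$group, levels = rev(.data$group)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$group,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b9e77",
                                          `FALSE` = "grey70"),
                               name = "significant") +
    ggplot2::labs(x = "Pearson r with phenotype", y = NULL,
                  title = "Gene-group / phenotype correlation scan") +
    ggplot2::theme_minimal()
}

#' Plot condition bimodality: RP versus AA modulation
#'
#' @param data output of [classify_condition_bimodal()].
#' @param theta the threshold used, drawn as dashed guides.
#' @return a ggplot.
#' @export
plot_bimodal <- function(data, theta = 0.5) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$delta_rp, y = .data$delta_aa,
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-theta, theta), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-theta, theta), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "RP mean log2 change", y = "AA mean log2 change",
                  title = "RP- vs AA-modulated conditions") +
    ggplot2::theme_minimal()
}
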