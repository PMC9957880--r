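#' Plot a calibrated failure model
#'
#' Mixture survival curve with its short- and long-term components.
#'
#' @param object A `failure_model`.
#' @param t_max Upper end of the time axis in years.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.failure_model <- function(object, t_max = 50, ...) {
  t <- seq(0, t_max, by = 0.25)
  df <- dplyr::bind_rows(
    tibble::tibble(t = t, survival = failure_survival(object, t),
                   curve = "mixture"),
    tibble::tibble(t = t, survival = weibull_survival(object$short, t),
                   curve = "short-term cause"),
    tibble::tibble(t = t, survival = weibull_survival(object$long, t),
                   curve = "long-term cause"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$survival,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "years since intervention", y = "survival",
                  linetype = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `maci_ceac` tibble from [compute_ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maci_ceac <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(.data$wtp_eur_per_qaly,
                 .data$probability_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "willingness to pay (EUR/QALY)",
                  y = "probability M-ACI is cost-effective") +
    ggplot2::ylim(0, 1)
}

#' Plot a tornado analysis
#'
#' Horizontal bars spanning the ICER at the low and high value of each
#' parameter, ordered by influence, with the baseline ICER as a
#' reference line.
#'
#' @param object A `maci_tornado` tibble from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maci_tornado <- function(object, ...) {
  df <- dplyr::mutate(object,
    parameter = factor(.data$parameter,
                       levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "grey60") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_baseline),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (EUR/QALY)", y = NULL)
}

#' Plot the incremental cost-effectiveness plane
#'
#' Per-patient incremental discounted QALYs against incremental
#' discounted costs, with the willingness-to-pay threshold line.
#'
#' @param object A `maci_sim` object.
#' @param wtp Willingness-to-pay threshold for the reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maci_sim <- function(object, wtp = 20000, ...) {
  ggplot2::ggplot(object$paired,
                  ggplot2::aes(.data$d_qaly, .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "incremental QALYs (discounted)",
                  y = "incremental cost (EUR, discounted)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
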