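#' Plot a simulated time course
#'
#' @param object A `kin_timecourse` from [simulate_scheme()].
#' @param log_time Use a logarithmic time axis (the t = 0 row is dropped).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_timecourse <- function(object, log_time = TRUE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "species", values_to = "conc")
  if (log_time) long <- dplyr::filter(long, .data$time > 0)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                          colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (uM)")
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot occupancy traces
#'
#' @param object A `kin_occupancy` from [occupancy()].
#' @param log_time Use a logarithmic time axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_occupancy <- function(object, log_time = TRUE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "metric", values_to = "fraction")
  if (log_time) long <- dplyr::filter(long, .data$time > 0)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$fraction,
                                          linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fraction of total enzyme")
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a dose-rate result
#'
#' Observed kobs per dose with the fitted Michaelis-Menten analog.
#'
#' @param object A `dose_rate_result` from [dose_rate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_rate_result <- function(object, ...) {
  grid <- tibble::tibble(dose = 10^seq(log10(min(object$data$dose)),
                                       log10(max(object$data$dose)),
                                       length.out = 200))
  grid$kobs <- object$mm$kinactapp * grid$dose /
    (object$mm$KIapp + grid$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$kobs)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[I]0 (uM)", y = "kobs (s^-1)")
}

#' Plot a dose-response result
#'
#' Simulated covalent occupancy at the stop time, with the analytic
#' Hill-form curve (amplitude and EC50 from the closed-form expressions).
#'
#' @param object A `dose_response_result` from [dose_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_result <- function(object, ...) {
  d <- tidy_dose_response(object)
  long <- tidyr::pivot_longer(d, c("co", "co_analytic"),
                              names_to = "source", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$dose, .data$value,
                                     linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[I]0 (uM)", y = "covalent occupancy at t_dr")
}

#' Plot a global-fit surface
#'
#' Observed versus fitted covalent occupancy, one facet per dose.
#'
#' @param object A `kin_global_fit` from [global_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_global_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$co)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$co_fitted), colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$dose), scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "covalent occupancy")
}
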