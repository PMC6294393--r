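#' Plot a nest input/output curve
#'
#' Draws `r_out` against `r_in` with the diagonal `r_in = r_out` as a
#' dashed reference; crossings of the diagonal are the candidate
#' steady-state foraging rates. Simulated curves show +/- 1 SE error bars.
#'
#' @param object A `nest_io_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.nest_io_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r_in,
                                            y = .data$r_out)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "incoming rate (ants/s)", y = "outgoing rate (ants/s)",
                  title = sprintf("nest I/O curve (%s)",
                                  attr(object, "mode")))
  if ("se" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r_out - .data$se,
                   ymax = .data$r_out + .data$se), width = 0.05)
  }
  p
}

#' Plot a closed-loop simulation record
#'
#' Either the time series of the incoming/outgoing rates with the number
#' of foragers outside, or the input-output trajectory (`r_out` vs `r_in`
#' coloured by time), the two standard views of colony foraging activity.
#'
#' @param object A `sim_record`.
#' @param type `"rates"` (default) or `"io"`.
#' @param window Rate window in seconds.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sim_record <- function(object, type = c("rates", "io"),
                                window = 300, ...) {
  type <- match.arg(type)
  df <- tidy(object, window = window)
  if (type == "rates") {
    long <- rbind(
      data.frame(time_s = df$time_s, value = df$r_in, series = "r_in"),
      data.frame(time_s = df$time_s, value = df$r_out, series = "r_out"))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600,
                                       y = .data$value,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::scale_colour_manual(values = c(r_in = "#2166ac",
                                              r_out = "#b2182b")) +
      ggplot2::labs(x = "time (h)", y = "foraging rate (ants/s)",
                    colour = NULL)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$r_in, y = .data$r_out,
                                     colour = .data$time_s / 3600)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey40") +
      ggplot2::geom_path() +
      ggplot2::labs(x = "incoming rate (ants/s)",
                    y = "outgoing rate (ants/s)", colour = "time (h)")
  }
}

#' Plot a stationary stimulus density
#'
#' @param object A `stimulus_density`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.stimulus_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stimulus s", y = "stationary density",
                  title = sprintf("r_in = %g ants/s", attr(object, "r_in")))
}
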