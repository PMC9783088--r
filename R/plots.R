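# ggplot2 views of the result types.

#' Plot a saturation field
#'
#' One saturation profile per output time, the classic wetting-front
#' "staircase" marching along the strip.
#'
#' @param object A `wick_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wick_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_m, y = .data$saturation,
                                   colour = factor(.data$time_s))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along strip (m)",
                  y = "wetting saturation",
                  colour = "time (s)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a simulation-versus-observation comparison
#'
#' Observed front positions as points, simulated as a line, per time.
#'
#' @param object A `wick_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wick_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated_m,
                                    linetype = "simulated")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_m,
                                     shape = "observed"), size = 2) +
    ggplot2::labs(x = "time (s)", y = "front position (m)",
                  linetype = NULL, shape = NULL,
                  title = if (is.na(object$membrane)) NULL else object$membrane) +
    ggplot2::theme_minimal()
}

#' Plot one or more wicking traces
#'
#' @param ... Named trace tibbles (`time_s`, `front_m`); names label the
#'   legend.
#' @return A ggplot.
#' @export
plot_wicking_traces <- function(...) {
  traces <- list(...)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- paste0("trace", seq_along(traces))
  }
  df <- dplyr::bind_rows(lapply(traces, function(tr) {
    tibble(time_s = tr$time_s, front_m = tr$front_m)
  }), .id = "trace")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$front_m,
                                   colour = .data$trace)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "front position (m)", colour = NULL) +
    ggplot2::theme_minimal()
}
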