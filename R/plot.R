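#' Plot a breathing signal
#'
#' @param object A `breathing_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breathing_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$pos_mm)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time [s]", y = "AP displacement [mm]") +
    ggplot2::theme_minimal()
}

#' Plot a cyclic decomposition
#'
#' Shows the signal with its envelopes and baseline, and the phase and
#' deflection channels, in stacked panels.
#'
#' @param object A `bc_decomp`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bc_decomp <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_s", "pos_mm", "baseline_mm",
                                "midline_mm", "phase_deg", "deflection_mm")],
    cols = -"time_s", names_to = "channel", values_to = "value"
  )
  long$panel <- dplyr::case_when(
    long$channel %in% c("pos_mm", "baseline_mm", "midline_mm") ~ "signal [mm]",
    long$channel == "phase_deg" ~ "phase [deg]",
    TRUE ~ "deflection [mm]"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a prediction trace
#'
#' Observed signal, prediction and pointwise error.
#'
#' @param object A `bc_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bc_prediction <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$error_mm <- df$y_pred_mm - df$pos_mm
  long <- tidyr::pivot_longer(df[c("time_s", "pos_mm", "y_pred_mm",
                                   "error_mm")],
                              cols = -"time_s",
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series == "error_mm", "error [mm]", "signal [mm]")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A `bc_predictor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bc_predictor <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, cols = -"epoch",
                              names_to = "series", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (scaled space)", colour = NULL) +
    ggplot2::theme_minimal()
}
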