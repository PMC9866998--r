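#' Plot an accelerometer recording
#'
#' Tri-axial traces, faceted by axis.
#'
#' @param object An [accel_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accel_recording
#' @export
autoplot.accel_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("ax", "ay", "az"),
                              names_to = "axis", values_to = "acceleration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$acceleration)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("acceleration (%s)",
                              ifelse(recording_units(object) == "g", "g",
                                     "m/s\u00b2"))) +
    ggplot2::theme_minimal()
}

#' Plot the CWT signal chain
#'
#' Integrated vertical acceleration and its two wavelet differentiations,
#' with detected initial (minima of `d1`) and final (maxima of `d2`)
#' contacts marked — the standard diagnostic view of the event detector.
#'
#' @param object A `cwt_signals` from [cwt_chain()].
#' @param cfg A [gait_config()] used for event marking.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cwt_signals
#' @export
autoplot.cwt_signals <- function(object, cfg = gait_config(), ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("y_int", "d1", "d2"),
                              names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, levels = c("y_int", "d1", "d2"))
  ev <- dplyr::bind_rows(
    tibble(t = detect_ic(object, cfg), signal = factor("d1", levels(long$signal)),
           event = "IC"),
    tibble(t = detect_fc(object, cfg), signal = factor("d2", levels(long$signal)),
           event = "FC"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(ev) > 0L) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$t,
                                              colour = .data$event),
                                 linetype = "dashed", alpha = 0.5) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot per-step characteristics over time
#'
#' One panel per characteristic, points coloured by side — the free-living
#' trace view in which step-length or timing anomalies stand out.
#'
#' @param object A `step_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot step_table
#' @export
autoplot.step_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    dplyr::any_of(GAIT_CHARACTERISTICS),
    names_to = "characteristic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$ic_time, .data$value,
                                     colour = .data$side)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~characteristic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "side") +
    ggplot2::theme_minimal()
}

#' Plot context-stratified domain characteristics
#'
#' Bar panel per domain, one bar per terrain and characteristic.
#'
#' @param object A `gait_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_analysis
#' @export
autoplot.gait_analysis <- function(object, ...) {
  dt <- tidy(object)
  if (!"terrain" %in% names(dt)) dt$terrain <- "all"
  agg <- dplyr::summarise(
    dplyr::group_by(dt, .data$terrain, .data$domain, .data$characteristic),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$characteristic, .data$value,
                                    fill = .data$terrain)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~domain, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, fill = "terrain") +
    ggplot2::theme_minimal()
}
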