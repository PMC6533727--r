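#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot normalized-red waveforms
#'
#' One panel per plot, normalized red value against time - the raw view in
#' which slow lighting drift and the faster canopy sway are both visible.
#'
#' @param object A `waveform_tbl`.
#' @param plots Optional subset of plot names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot waveform_tbl
#' @export
autoplot.waveform_tbl <- function(object, plots = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(plots)) d <- d[d$plot %in% plots, ]
  ggplot(d, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~plot, scales = "free_y") +
    labs(x = "Time (s)", y = "Normalized red value") +
    theme_minimal()
}

#' Plot a filtered waveform with its detected peaks
#'
#' @param filtered Zero-centered filtered waveform.
#' @param frame_rate_fps Frames per second.
#' @param min_prominence Peak prominence threshold.
#' @return A ggplot object.
#' @export
plot_cycles <- function(filtered, frame_rate_fps = 24, min_prominence = 0.005) {
  cyc <- detect_cycles(filtered, frame_rate_fps, min_prominence)
  peaks <- attr(cyc, "peaks")
  t <- (seq_along(filtered) - 1) / frame_rate_fps
  d <- tibble(time_s = t, value = filtered)
  p <- ggplot(d, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (s)", y = "Filtered normalized red") +
    theme_minimal()
  if (length(peaks) > 0) {
    p <- p + geom_point(data = d[peaks, ], colour = "red", size = 1)
  }
  p
}

#' Plot binned movement amplitude per plot
#'
#' Column chart of the 0.2 Hz amplitude bins from a movement summary.
#'
#' @param summary Tibble from [analyze_movement()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_bin_areas <- function(summary, ...) {
  bins <- grep("^bin_", names(summary), value = TRUE)
  long <- tidyr::pivot_longer(summary[, c("plot", bins)], all_of(bins),
                              names_to = "bin", values_to = "area")
  long$freq <- as.numeric(sub("bin_([0-9.]+)_.*", "\\1", long$bin)) + 0.1
  ggplot(long, aes(x = .data$freq, y = .data$area)) +
    geom_col(width = 0.18) +
    facet_wrap(~plot) +
    labs(x = "Frequency bin center (Hz)",
         y = "Amplitude (percent normalized red)") +
    theme_minimal()
}
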