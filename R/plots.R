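#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

state_palette <- function() {
  c(WAKE = "#D55E00", NREM = "#0072B2", REM = "#009E73",
    ARTIFACT = "grey70", SLEEP = "#0072B2")
}

#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  ep <- hyp_epoch_s(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(xmin = .data$start_s, xmax = .data$start_s + ep,
                               ymin = 0, ymax = 1, fill = .data$state)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = state_palette()) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @method autoplot zscore_trace
#' @export
autoplot.zscore_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trial, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "z-scored fluorescence") +
    ggplot2::theme_minimal()
}

#' @method autoplot transient_set
#' @export
autoplot.transient_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$peak_time_s, .data$peak_z,
                               size = .data$prominence)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "peak time (s)", y = "peak z", size = "prominence") +
    ggplot2::theme_minimal()
}

#' @method autoplot psd
#' @export
autoplot.psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density") +
    ggplot2::theme_minimal()
}

#' @method autoplot spectrogram
#' @export
autoplot.spectrogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_s, .data$freq_hz,
                               fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @method autoplot fi_curve
#' @export
autoplot.fi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$current_pA, .data$rate_hz)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @method autoplot transition_trace_set
#' @export
autoplot.transition_trace_set <- function(object, ...) {
  d <- tibble::tibble(
    event = rep(seq_len(nrow(object$traces)), times = ncol(object$traces)),
    time_rel_s = rep(object$time_rel_s, each = nrow(object$traces)),
    z = as.numeric(object$traces)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time_rel_s, .data$event,
                                  fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_viridis_c(name = "norm. z") +
    ggplot2::labs(x = "time from transition (s)", y = "event") +
    ggplot2::theme_minimal()
}

#' @method autoplot locomotor_series
#' @export
autoplot.locomotor_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_start_s / 3600, .data$counts)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "beam breaks / 10 s") +
    ggplot2::theme_minimal()
}
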