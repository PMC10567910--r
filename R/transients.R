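#' Find peaks with topographic prominence and width
#'
#' Locates interior local maxima (leftmost sample of plateaus), computes
#' each peak's topographic prominence — its height above the higher of the
#' two lowest levels separating it from the nearest higher samples on
#' either side, or the trace ends — and its width at half prominence by
#' linear interpolation. This mirrors the classic `findpeaks` behaviour
#' used for Ca2+ transient screening.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz) used to express times/widths in seconds.
#' @return Tibble with `index` (1-based sample), `time_s`, `value`,
#'   `prominence`, `width_s`, one row per local maximum (unfiltered).
#' @examples
#' x <- dnorm(seq(-3, 3, length.out = 101))
#' find_peaks(x, fs = 10)
#' @export
find_peaks <- function(x, fs = 1) {
  if (!length(x)) {
    return(tibble::tibble(index = integer(), time_s = numeric(),
                          value = numeric(), prominence = numeric(),
                          width_s = numeric()))
  }
  if (!all(is.finite(x))) stop("non-finite samples in input", call. = FALSE)
  pk <- cpp_find_peaks(as.numeric(x))
  tibble::tibble(index = pk$index,
                 time_s = (pk$index - 1) / fs,
                 value = x[pk$index],
                 prominence = pk$prominence,
                 width_s = pk$width_samples / fs)
}

#' Detect Ca2+ transients in a z-scored photometry trace
#'
#' Screens the local maxima of the z-score trace, keeping peaks whose
#' topographic prominence and half-prominence width exceed the thresholds
#' (defaults: prominence 0.1 z, width 80 ms). Detection runs per trial
#' segment so that peaks never straddle inter-trial gaps.
#'
#' @param z A `zscore_trace` from [preprocess_photometry()], or any tibble
#'   with `time_s`, `z` and (optionally) `trial` columns plus an `fs`
#'   attribute.
#' @param min_width_s Minimum peak width at half prominence (s).
#' @param min_prominence Minimum topographic prominence (z units).
#' @return A `transient_set` tibble: `trial`, `peak_time_s`, `peak_z`,
#'   `prominence`, `width_s`, ordered by peak time; attributes `fs` and
#'   `trial_windows`.
#' @export
detect_transients <- function(z, min_width_s = 0.08, min_prominence = 0.1) {
  stopifnot(min_width_s > 0, min_prominence > 0)
  fs <- trace_fs(z)
  if (!"trial" %in% names(z)) z$trial <- 1L
  out <- dplyr::group_modify(
    dplyr::group_by(z, .data$trial),
    function(d, g) {
      pk <- find_peaks(d$z, fs = fs)
      pk <- pk[pk$prominence >= min_prominence & pk$width_s >= min_width_s, ]
      tibble::tibble(peak_time_s = d$time_s[pk$index],
                     peak_z = pk$value,
                     prominence = pk$prominence,
                     width_s = pk$width_s)
    }
  )
  out <- dplyr::arrange(dplyr::ungroup(out), .data$peak_time_s)
  attr(out, "fs") <- fs
  attr(out, "trial_windows") <- attr(z, "trial_windows")
  attr(out, "trace_duration_s") <- nrow(z) / fs
  class(out) <- c("transient_set", class(out))
  out
}

#' Construct a transient set from explicit values
#'
#' Builds the same structure [detect_transients()] returns, for transients
#' obtained elsewhere (e.g. loaded from CSV).
#'
#' @param peak_time_s Peak times (s, photometry clock), increasing.
#' @param prominence Topographic prominences (z units).
#' @param peak_z,width_s Optional peak heights and widths.
#' @param trial Trial index per transient.
#' @param trial_windows Tibble of `start_s`, `end_s` trial windows the
#'   peaks were recorded in.
#' @param fs Sampling rate (Hz).
#' @return A `transient_set` tibble.
#' @export
new_transient_set <- function(peak_time_s, prominence,
                              peak_z = prominence, width_s = NA_real_,
                              trial = 1L,
                              trial_windows = NULL, fs = NA_real_) {
  out <- tibble::tibble(trial = trial, peak_time_s = peak_time_s,
                        peak_z = peak_z, prominence = prominence,
                        width_s = width_s)
  if (is.null(trial_windows))
    trial_windows <- tibble::tibble(trial = 1L, start_s = 0,
                                    end_s = max(peak_time_s, 0) + 1)
  attr(out, "trial_windows") <- trial_windows
  attr(out, "fs") <- fs
  class(out) <- c("transient_set", class(out))
  out
}

# seconds of non-ARTIFACT time per state within the (EEG-clock) intervals
# actually covered by the photometry trace
state_time_in_intervals <- function(hyp, intervals_eeg) {
  ep <- hyp_epoch_s(hyp)
  starts <- hyp$start_s
  ends <- starts + ep
  secs <- stats::setNames(numeric(length(sleep_states())), sleep_states())
  for (k in seq_len(nrow(intervals_eeg))) {
    ov <- pmin(ends, intervals_eeg$end_s[k]) -
      pmax(starts, intervals_eeg$start_s[k])
    ov[ov < 0] <- 0
    for (s in sleep_states())
      secs[s] <- secs[s] + sum(ov[hyp$state == s])
  }
  secs
}

# trial windows of a transient set / z-trace mapped onto the EEG clock
mapped_trial_intervals <- function(x, map) {
  tw <- attr(x, "trial_windows")
  if (is.null(tw))
    stop("object lacks trial window information", call. = FALSE)
  tibble::tibble(start_s = map_time(map, tw$start_s),
                 end_s = map_time(map, tw$end_s))
}

#' Per-state transient rates
#'
#' Assigns each detected transient to the vigilance state of the scored
#' epoch containing its (clock-mapped) peak time, and divides by the
#' non-ARTIFACT time spent in that state within the recorded trial
#' windows. Transients mapping outside the scored span, or into ARTIFACT
#' epochs, are excluded with a warning.
#'
#' @param ts A `transient_set` from [detect_transients()].
#' @param hyp A hypnogram on the EEG clock.
#' @param map A `clock_map` (default: identity).
#' @param deadtime_s Optional dead-time correction (s). Peak counting
#'   cannot resolve transients closer together than roughly the transient
#'   width, so at high rates the raw peak rate undercounts the underlying
#'   event rate like a paralyzable dead-time counter,
#'   `r_observed = lambda * exp(-lambda * deadtime_s)`. With
#'   `deadtime_s > 0` (the transient full width at half maximum is the
#'   natural choice) the returned rates are the inverted `lambda`;
#'   the default 0 reports the raw peak rate.
#' @return Tibble `state`, `n`, `minutes`, `rate_per_min` (NA rate where a
#'   state has zero scored time).
#' @export
transient_rate_by_state <- function(ts, hyp, map = identity_clock_map(),
                                    deadtime_s = 0) {
  st <- hyp_state_at(hyp, map_time(map, ts$peak_time_s))
  n_out <- sum(is.na(st))
  if (n_out > 0)
    warning(n_out, " transient(s) map outside the scored hypnogram span",
            call. = FALSE)
  secs <- state_time_in_intervals(hyp, mapped_trial_intervals(ts, map))
  counts <- vapply(sleep_states(), function(s) sum(st == s, na.rm = TRUE), 0L)
  rate_hz <- unname(ifelse(secs > 0, counts / secs, NA_real_))
  if (deadtime_s > 0)
    rate_hz <- vapply(rate_hz, deadtime_invert, 0, tau = deadtime_s)
  tibble::tibble(
    state = sleep_states(),
    n = as.integer(counts),
    minutes = as.numeric(secs) / 60,
    rate_per_min = 60 * rate_hz
  )
}

# invert r = lambda * exp(-lambda * tau) for lambda on the principal branch
# (lambda * tau < 1); observed rates beyond the counter maximum 1/(e*tau)
# saturate at lambda = 1/tau
deadtime_invert <- function(r, tau) {
  if (!is.finite(r) || r <= 0) return(r)
  if (r >= exp(-1) / tau) return(1 / tau)
  stats::uniroot(function(l) l * exp(-l * tau) - r,
                 lower = r, upper = 1 / tau, tol = 1e-12)$root
}

#' Per-state mean transient prominence
#'
#' As [transient_rate_by_state()], but averages the topographic prominence
#' of the transients assigned to each state; states without transients get
#' NA.
#'
#' @inheritParams transient_rate_by_state
#' @return Tibble `state`, `n`, `mean_prominence`.
#' @export
transient_prominence_by_state <- function(ts, hyp, map = identity_clock_map()) {
  st <- hyp_state_at(hyp, map_time(map, ts$peak_time_s))
  tibble::tibble(
    state = sleep_states(),
    n = unname(vapply(sleep_states(), function(s) sum(st == s, na.rm = TRUE), 0L)),
    mean_prominence = unname(vapply(sleep_states(), function(s) {
      v <- ts$prominence[!is.na(st) & st == s]
      if (length(v)) mean(v) else NA_real_
    }, 0))
  )
}

#' Per-state mean z-score
#'
#' Mean of the z-scored fluorescence over all samples falling in
#' non-ARTIFACT epochs of each state. With `by_trial = TRUE` the mean is
#' computed per trial and state (hierarchical averaging: trials can then
#' be averaged per animal).
#'
#' @param z A `zscore_trace`.
#' @inheritParams transient_rate_by_state
#' @param by_trial Return per-trial state means instead of pooled means.
#' @return Tibble `state`, `mean_z` (plus `trial` if `by_trial`); states
#'   with no samples get NA.
#' @export
zscore_by_state <- function(z, hyp, map = identity_clock_map(),
                            by_trial = FALSE) {
  st <- hyp_state_at(hyp, map_time(map, z$time_s))
  d <- tibble::tibble(trial = if ("trial" %in% names(z)) z$trial else 1L,
                      state = st, z = z$z)
  d <- d[!is.na(d$state) & d$state != "ARTIFACT", ]
  if (by_trial) {
    out <- dplyr::summarise(dplyr::group_by(d, .data$trial, .data$state),
                            mean_z = mean(.data$z), .groups = "drop")
  } else {
    out <- dplyr::summarise(dplyr::group_by(d, .data$state),
                            mean_z = mean(.data$z), .groups = "drop")
    out <- dplyr::left_join(tibble::tibble(state = sleep_states()), out,
                            by = "state")
  }
  out
}
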