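#' Total locomotor activity in circadian windows
#'
#' Sums beam-break counts over circadian-time windows (hours; e.g.
#' `list(day = c(0, 12), night = c(12, 24))`). Window membership is by
#' clock time modulo 24 h, so multi-day series accumulate every matching
#' bin; only bins falling entirely inside a window are counted.
#'
#' @param series A `locomotor_series` tibble (`ct_h`, `counts`) with a
#'   `bin_s` attribute.
#' @param windows Named list of `c(start_h, end_h)` windows with
#'   `0 <= start < end <= 24`.
#' @return Tibble `window`, `n_bins`, `total`.
#' @export
locomotor_totals <- function(series, windows) {
  bin_h <- (attr(series, "bin_s") %||% 10) / 3600
  out <- purrr::imap_dfr(windows, function(w, nm) {
    if (w[1] < 0 || w[2] <= w[1] || w[2] > 24)
      stop("window must satisfy 0 <= start < end <= 24 (hours)", call. = FALSE)
    sel <- series$ct_h >= w[1] & (series$ct_h + bin_h) <= w[2] + 1e-9
    if (!any(sel))
      stop("window [", w[1], ", ", w[2], ") contains no complete bins",
           call. = FALSE)
    tibble::tibble(window = nm, n_bins = sum(sel),
                   total = sum(series$counts[sel]))
  })
  out
}

#' Mean 24-h locomotor activity profile
#'
#' Averages counts at each clock time of day across the days in the
#' series, with optional centred moving-average smoothing (circular, so
#' midnight joins up).
#'
#' @param series A `locomotor_series` spanning at least 24 h.
#' @param smooth_bins Width of the moving average in bins (1 = none).
#' @return Tibble `ct_h`, `mean_counts`.
#' @export
locomotor_profile <- function(series, smooth_bins = 1) {
  bin_s <- attr(series, "bin_s") %||% 10
  per_day <- as.integer(24 * 3600 / bin_s)
  if (nrow(series) < per_day)
    stop("profile needs at least 24 h of data", call. = FALSE)
  slot <- as.integer(round((series$ct_h * 3600) / bin_s)) %% per_day
  prof <- tapply(series$counts, slot, mean)
  ct <- as.numeric(names(prof)) * bin_s / 3600
  y <- as.numeric(prof)
  if (smooth_bins > 1) {
    k <- as.integer(smooth_bins)
    half <- k %/% 2
    ext <- c(utils::tail(y, half), y, utils::head(y, half))
    y <- stats::filter(ext, rep(1 / k, k), sides = 2)[(half + 1):(half + length(prof))]
  }
  tibble::tibble(ct_h = ct, mean_counts = as.numeric(y))
}

#' Startle response quantification with pre-tone exclusion
#'
#' `Vavg` is the mean rectified platform voltage over the 100 ms window
#' after the tone. A trial is excluded when the RMS of the 100 ms window
#' before the tone exceeds `exclusion_factor` times the session baseline
#' RMS (significant pre-tone vibration).
#'
#' @param trace Platform voltage (mV).
#' @param fs Sampling rate (Hz).
#' @param tone_onset_s Tone onset within the trace (s).
#' @param baseline_rms_mv Session baseline RMS (mV); see
#'   [analyze_startle()] for the session-level estimate.
#' @param pre_window_s Pre-tone scan window (s, default 0.1).
#' @param response_window_s Response window (s, default 0.1).
#' @param exclusion_factor Multiple of the baseline RMS that triggers
#'   exclusion (default 3).
#' @return Tibble row: `vavg_mv`, `pre_rms_mv`, `excluded`.
#' @export
startle_vavg <- function(trace, fs, tone_onset_s, baseline_rms_mv,
                         pre_window_s = 0.1, response_window_s = 0.1,
                         exclusion_factor = 3) {
  t <- (seq_along(trace) - 1) / fs
  if (tone_onset_s - pre_window_s < -1e-9 ||
      tone_onset_s + response_window_s > t[length(t)] + 1e-9)
    stop("trace does not span the pre-tone and response windows", call. = FALSE)
  resp <- trace[t > tone_onset_s & t <= tone_onset_s + response_window_s]
  pre <- trace[t > tone_onset_s - pre_window_s & t <= tone_onset_s]
  pre_rms <- sqrt(mean(pre^2))
  tibble::tibble(
    vavg_mv = mean(abs(resp)),
    pre_rms_mv = pre_rms,
    excluded = is.finite(baseline_rms_mv) &&
      pre_rms > exclusion_factor * baseline_rms_mv
  )
}

#' Quantify a startle session
#'
#' Computes `Vavg` and the exclusion flag for every trial. The session
#' baseline RMS is the median of the per-trial pre-tone RMS values — a
#' robust estimate of resting sensor noise that tolerates a minority of
#' contaminated trials.
#'
#' @param startle A startle-trial tibble as from [generate_behavior()]:
#'   columns `trial`, `tone_db`, `tone_onset_s` and a `trace` list-column,
#'   with an `fs` attribute (or pass `fs`).
#' @param fs Sampling rate (Hz); defaults to the table's `fs` attribute.
#' @inheritParams startle_vavg
#' @return Tibble `trial`, `tone_db`, `vavg_mv`, `pre_rms_mv`, `excluded`.
#' @export
analyze_startle <- function(startle, fs = NULL, pre_window_s = 0.1,
                            response_window_s = 0.1, exclusion_factor = 3) {
  fs <- fs %||% attr(startle, "fs") %||% stop("supply fs")
  pre_rms <- vapply(seq_len(nrow(startle)), function(i) {
    tr <- startle$trace[[i]]
    t <- (seq_along(tr) - 1) / fs
    o <- startle$tone_onset_s[i]
    sqrt(mean(tr[t > o - pre_window_s & t <= o]^2))
  }, 0)
  baseline <- stats::median(pre_rms)
  rows <- purrr::map_dfr(seq_len(nrow(startle)), function(i) {
    startle_vavg(startle$trace[[i]], fs, startle$tone_onset_s[i],
                 baseline_rms_mv = baseline, pre_window_s = pre_window_s,
                 response_window_s = response_window_s,
                 exclusion_factor = exclusion_factor)
  })
  dplyr::bind_cols(
    tibble::tibble(trial = startle$trial, tone_db = startle$tone_db), rows
  )
}
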