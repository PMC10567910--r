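#' Identify sleep/wake bouts
#'
#' A bout is a maximal run of identical non-ARTIFACT epoch labels lasting
#' strictly more than `min_duration_s` (default 30 s, i.e. at least four
#' 10-s epochs). In `mode = "sleep"` NREM and REM runs are first merged
#' into a single SLEEP label, so bouts of continuous sleep are scored
#' regardless of stage; the default scores each state separately.
#'
#' @param hyp A hypnogram tibble (see [new_hypnogram()]).
#' @param min_duration_s Strict lower bound on bout duration (s).
#' @param mode `"state"` (default) or `"sleep"`.
#' @param inclusive If TRUE the bound is `>=` instead of the literal `>`.
#' @return Tibble `state`, `start_s`, `end_s`, `duration_s`.
#' @examples
#' hyp <- new_hypnogram(c("WAKE", "WAKE", "WAKE", "WAKE", "NREM"))
#' find_bouts(hyp)
#' @export
find_bouts <- function(hyp, min_duration_s = 30,
                       mode = c("state", "sleep"), inclusive = FALSE) {
  mode <- match.arg(mode)
  ep <- hyp_epoch_s(hyp)
  labels <- hyp$state
  if (mode == "sleep") labels[labels %in% c("NREM", "REM")] <- "SLEEP"
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- r$lengths * ep
  keep <- r$values != "ARTIFACT" &
    (if (inclusive) dur >= min_duration_s else dur > min_duration_s)
  tibble::tibble(
    state = r$values[keep],
    start_s = hyp$start_s[starts[keep]],
    end_s = hyp$start_s[starts[keep]] + dur[keep],
    duration_s = dur[keep]
  )
}

#' Percentage of time in a state, per time bin
#'
#' Splits the hypnogram into bins of `bin_s` seconds (a multiple of the
#' epoch length) and reports the percentage of non-ARTIFACT epochs in each
#' bin labelled `state`. Bins containing only ARTIFACT epochs are NA.
#'
#' @param hyp A hypnogram.
#' @param state State to score (WAKE, NREM or REM).
#' @param bin_s Bin width in seconds (e.g. 3600 for 1-h bins, 60 for
#'   1-min bins).
#' @return Tibble `bin_start_s`, `n_scored` (non-ARTIFACT epochs),
#'   `percent`.
#' @export
percent_state_binned <- function(hyp, state, bin_s) {
  ep <- hyp_epoch_s(hyp)
  k <- bin_s / ep
  if (abs(k - round(k)) > 1e-9)
    stop("bin_s must be a multiple of the epoch length", call. = FALSE)
  state <- match.arg(state, sleep_states())
  bin <- floor((hyp$start_s - hyp_t0_s(hyp)) / bin_s)
  d <- tibble::tibble(bin = bin, st = hyp$state)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$bin),
    n_scored = sum(.data$st != "ARTIFACT"),
    percent = ifelse(.data$n_scored > 0,
                     100 * sum(.data$st == state) / .data$n_scored,
                     NA_real_),
    .groups = "drop"
  )
  tibble::tibble(bin_start_s = hyp_t0_s(hyp) + out$bin * bin_s,
                 n_scored = out$n_scored, percent = out$percent)
}

#' Latency to arousal from NREM sleep
#'
#' Time from a stimulation onset to the start of the first WAKE epoch at
#' or after it. The epoch containing the onset must be scored NREM (the
#' animal must be asleep at stimulus onset), otherwise the trial is
#' rejected with an error.
#'
#' @param hyp A hypnogram.
#' @param stim_onset_s Stimulation onset (s, EEG clock).
#' @return Latency in seconds, or NA if no WAKE epoch follows within the
#'   scored record.
#' @export
latency_to_arousal <- function(hyp, stim_onset_s) {
  st0 <- hyp_state_at(hyp, stim_onset_s)
  if (is.na(st0))
    stop("stimulus onset outside the scored record", call. = FALSE)
  if (st0 != "NREM")
    stop("trial rejected: state at stimulus onset is ", st0,
         ", not NREM", call. = FALSE)
  idx <- which(hyp$state == "WAKE" & hyp$start_s >= stim_onset_s)
  if (!length(idx)) return(NA_real_)
  hyp$start_s[idx[1]] - stim_onset_s
}

#' Welch power spectral density
#'
#' Welch's method: the trace is split into Hann-windowed segments of
#' `nfft` samples with 50% overlap; the one-sided periodograms (density
#' scaling, power per Hz) are averaged.
#'
#' @param x Numeric trace (at least `nfft` samples).
#' @param fs Sampling rate (Hz).
#' @param nfft Segment/FFT size; 512 or 1024 unless
#'   `allow_any_nfft = TRUE`.
#' @param allow_any_nfft Permit other segment sizes.
#' @return A `psd` tibble with `freq_hz` and `power` (input units^2 / Hz);
#'   attributes `fs`, `nfft`.
#' @export
welch_psd <- function(x, fs, nfft = 1024, allow_any_nfft = FALSE) {
  if (!allow_any_nfft && !nfft %in% c(512, 1024))
    stop("nfft must be 512 or 1024 (set allow_any_nfft = TRUE to override)",
         call. = FALSE)
  n <- length(x)
  if (n < nfft) stop("trace shorter than one segment", call. = FALSE)
  w <- hann_window(nfft)
  hop <- nfft / 2
  nseg <- floor((n - nfft) / hop) + 1
  acc <- numeric(nfft)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * hop + 1):((s - 1) * hop + nfft)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (nseg * fs * sum(w^2))
  half <- nfft / 2 + 1
  p1 <- pxx[1:half]
  p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
  out <- tibble::tibble(freq_hz = (0:(half - 1)) * fs / nfft, power = p1)
  attr(out, "fs") <- fs
  attr(out, "nfft") <- nfft
  class(out) <- c("psd", class(out))
  out
}

# periodic Hann window (matches FFT-analysis convention)
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Short-time Fourier spectrogram
#'
#' Magnitude-squared STFT with a Hann analysis window (default 30 s) and
#' 60% overlap, density-scaled like [welch_psd()], then smoothed along
#' time with a rolling Hann-weighted average (default 5 bins).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param window_s Analysis window length (s).
#' @param overlap Fractional overlap in `[0, 0.95]` (default 0.6).
#' @param smooth_bins Width of the rolling Hann smoother across time bins;
#'   1 disables smoothing.
#' @param max_freq_hz Optional frequency ceiling for the returned matrix.
#' @return A `spectrogram` tibble in long form (`time_s`, `freq_hz`,
#'   `power`) with attributes `times_s`, `freqs_hz`, `power` (matrix
#'   freq x time), `fs`.
#' @export
spectrogram_stft <- function(x, fs, window_s = 30, overlap = 0.6,
                             smooth_bins = 5, max_freq_hz = NULL) {
  if (overlap < 0 || overlap > 0.95)
    stop("overlap must lie in [0, 0.95]", call. = FALSE)
  W <- as.integer(round(window_s * fs))
  if (length(x) < W) stop("trace shorter than one window", call. = FALSE)
  hop <- max(1L, as.integer(round(W * (1 - overlap))))
  ncol_ <- floor((length(x) - W) / hop) + 1
  w <- hann_window(W)
  half <- floor(W / 2) + 1
  P <- matrix(0, nrow = half, ncol = ncol_)
  for (j in seq_len(ncol_)) {
    seg <- x[((j - 1) * hop + 1):((j - 1) * hop + W)] * w
    sp <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    p1 <- sp[1:half]
    p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
    P[, j] <- p1
  }
  freqs <- (0:(half - 1)) * fs / W
  times <- (seq_len(ncol_) - 1) * hop / fs + window_s / 2
  if (smooth_bins > 1) P <- roll_hann_smooth(P, smooth_bins)
  if (!is.null(max_freq_hz)) {
    keep <- freqs <= max_freq_hz
    P <- P[keep, , drop = FALSE]
    freqs <- freqs[keep]
  }
  out <- tibble::tibble(
    time_s = rep(times, each = length(freqs)),
    freq_hz = rep(freqs, times = length(times)),
    power = as.numeric(P)
  )
  attr(out, "times_s") <- times
  attr(out, "freqs_hz") <- freqs
  attr(out, "power") <- P
  attr(out, "fs") <- fs
  class(out) <- c("spectrogram", class(out))
  out
}

# rolling Hann-weighted average along the columns (time axis) of P,
# renormalized at the edges
roll_hann_smooth <- function(P, width) {
  w <- hann_window_sym(width)
  w <- w / sum(w)
  half <- (width - 1) %/% 2
  nc <- ncol(P)
  out <- matrix(0, nrow(P), nc)
  for (j in seq_len(nc)) {
    lo <- max(1, j - half)
    hi <- min(nc, j + half)
    ww <- w[(lo - j + half + 1):(hi - j + half + 1)]
    out[, j] <- P[, lo:hi, drop = FALSE] %*% (ww / sum(ww))
  }
  out
}

# symmetric Hann (nonzero at the ends for small widths)
hann_window_sym <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) + 1e-12
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the power spectral density over `[lo_hz, hi_hz)`,
#' with interpolated band edges so that a flat density `c` integrates to
#' exactly `c * (hi - lo)`.
#'
#' @param psd A `psd` tibble from [welch_psd()].
#' @param lo_hz,hi_hz Band edges (Hz), `0 <= lo < hi <= fs/2`.
#' @return Integrated power (input units squared).
#' @export
bandpower <- function(psd, lo_hz, hi_hz) {
  if (!(lo_hz >= 0 && hi_hz > lo_hz))
    stop("band edges must satisfy 0 <= lo < hi", call. = FALSE)
  f <- psd$freq_hz
  p <- psd$power
  if (hi_hz > max(f) + 1e-9)
    stop("hi_hz exceeds the Nyquist frequency of the PSD", call. = FALSE)
  inside <- f > lo_hz & f < hi_hz
  fx <- c(lo_hz, f[inside], hi_hz)
  px <- c(stats::approx(f, p, lo_hz, rule = 2)$y, p[inside],
          stats::approx(f, p, hi_hz, rule = 2)$y)
  pracma::trapz(fx, px)
}

#' Relative EMG amplitude around a stimulation
#'
#' EMG amplitude is the per-epoch RMS of the 10 Hz-high-passed EMG. Each
#' window's mean epoch amplitude is normalized to the mean amplitude over
#' the NREM epochs inside the `pre` window, so the pre-stimulation NREM
#' baseline maps to 1.
#'
#' @param emg Numeric EMG trace on the EEG clock starting at the
#'   hypnogram origin.
#' @param fs Sampling rate (Hz).
#' @param hyp A hypnogram.
#' @param windows Named list of `c(start_s, end_s)` windows (must include
#'   `pre`; typically also `stim` and `post`).
#' @param highpass_hz High-pass cutoff applied before the RMS (default 10).
#' @return Tibble `window`, `n_epochs`, `value` (dimensionless). If the
#'   pre window has no NREM epochs all values are NA, with a warning.
#' @export
relative_emg_amplitude <- function(emg, fs, hyp, windows, highpass_hz = 10) {
  stopifnot("pre" %in% names(windows))
  x <- zerophase_filter(signal::butter(4, highpass_hz / (fs / 2),
                                       type = "high"), emg)
  ep <- hyp_epoch_s(hyp)
  n_ep <- min(nrow(hyp), floor(length(x) / (ep * fs)))
  idx <- rep(seq_len(n_ep), each = as.integer(ep * fs))
  rms <- sqrt(tapply(x[seq_along(idx)]^2, idx, mean))
  ep_start <- hyp$start_s[seq_len(n_ep)]
  ep_state <- hyp$state[seq_len(n_ep)]

  in_window <- function(w) ep_start >= w[1] & (ep_start + ep) <= w[2]
  pre_nrem <- in_window(windows$pre) & ep_state == "NREM"
  if (!any(pre_nrem)) {
    warning("no NREM epochs in the pre window: relative EMG amplitude undefined",
            call. = FALSE)
    norm <- NA_real_
  } else {
    norm <- mean(rms[pre_nrem])
  }
  tibble::tibble(
    window = names(windows),
    n_epochs = unname(vapply(windows, function(w) sum(in_window(w)), 0L)),
    value = unname(vapply(windows, function(w) {
      sel <- in_window(w)
      if (!any(sel)) return(NA_real_)
      mean(rms[sel]) / norm
    }, 0))
  )
}
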