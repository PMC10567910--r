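#' Simulate an EEG/EMG record matching a hypnogram
#'
#' EEG is a mixture of three unit-variance band-limited noise processes
#' (delta 0.5-4 Hz, theta 5-9 Hz, broadband) whose weights switch with the
#' hypnogram state: delta dominates NREM, theta dominates REM, wake is
#' broadband with a theta component. EMG is white noise with a
#' state-dependent envelope (WAKE >> NREM > REM atonia). The acquisition
#' high-pass filters (0.5 Hz EEG, 10 Hz EMG) are applied, and a TTL channel
#' carries the synchronization pulse train on the EEG clock, shifted and
#' stretched by the configured clock offset/drift.
#'
#' @param cfg A [synth_config()].
#' @param hyp Hypnogram on the EEG clock; the record covers its span.
#' @param band_weights Optional 4x3 matrix (rows WAKE/NREM/REM/ARTIFACT,
#'   cols delta/theta/broad) overriding the default state band weights.
#' @return Tibble `time_s`, `eeg`, `emg`, `ttl` with attribute `fs` (400 Hz),
#'   class `eeg_record`.
#' @examples
#' cfg <- synth_config(seed = 4, n_trials = 1, trial_on_s = 60)
#' rec <- generate_eeg_emg(cfg, generate_hypnogram(cfg, 60))
#' attr(rec, "fs")
#' @export
generate_eeg_emg <- function(cfg, hyp, band_weights = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(hyp, "hypnogram"))
  fs <- cfg$eeg_fs_hz
  dur <- nrow(hyp) * hyp_epoch_s(hyp)
  n <- as.integer(round(dur * fs))
  t <- hyp_t0_s(hyp) + (seq_len(n) - 1) / fs

  if (is.null(band_weights)) {
    band_weights <- rbind(
      WAKE     = c(delta = 0.5, theta = 1.5, broad = 2.0),
      NREM     = c(delta = 3.0, theta = 0.5, broad = 1.0),
      REM      = c(delta = 0.5, theta = 3.0, broad = 1.0),
      ARTIFACT = c(delta = 1.0, theta = 1.0, broad = 8.0)
    )
  }

  withr_seed(cfg$seed, "eeg", {
    nyq <- fs / 2
    delta <- unit_sd(bandpass_noise(n, c(0.5, 4) / nyq))
    theta <- unit_sd(bandpass_noise(n, c(5, 9) / nyq))
    broad <- stats::rnorm(n)

    state <- hyp_state_at(hyp, t)
    state[is.na(state)] <- "WAKE"
    w <- band_weights[state, , drop = FALSE]
    eeg_scale <- 30  # microvolt scale of the unit-variance mixture
    eeg <- eeg_scale * (w[, "delta"] * delta + w[, "theta"] * theta +
                          w[, "broad"] * broad)

    emg_scale <- 20
    env <- cfg$emg_level[state]
    env[is.na(env)] <- max(cfg$emg_level)
    emg <- emg_scale * as.numeric(env) * stats::rnorm(n)

    # acquisition high-pass: 0.5 Hz EEG, 10 Hz EMG
    eeg <- zerophase_filter(signal::butter(2, 0.5 / nyq, type = "high"), eeg)
    emg <- zerophase_filter(signal::butter(2, 10 / nyq, type = "high"), emg)

    drift <- 1 + cfg$clock_drift_ppm * 1e-6
    phot_onsets <- seq(0, session_duration_s(cfg) - cfg$ttl_width_s,
                       by = cfg$ttl_period_s)
    eeg_onsets <- cfg$clock_offset_s + drift * phot_onsets
    eeg_onsets <- eeg_onsets[eeg_onsets >= t[1] & eeg_onsets <= t[n] - cfg$ttl_width_s]
    ttl <- pulse_train(t, eeg_onsets, cfg$ttl_width_s * drift)

    rec <- tibble::tibble(time_s = t, eeg = eeg, emg = emg, ttl = ttl)
    attr(rec, "fs") <- fs
    attr(rec, "ttl_onsets_s") <- eeg_onsets
    class(rec) <- c("eeg_record", class(rec))
    rec
  })
}

# white noise band-passed with a 4th-order Butterworth (normalized band W)
bandpass_noise <- function(n, W) {
  zerophase_filter(signal::butter(4, W, type = "pass"), stats::rnorm(n))
}

unit_sd <- function(x) x / stats::sd(x)
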