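#' Simulate a dual-channel fiber-photometry session
#'
#' Generates demodulated 465 nm (Ca2+-dependent) and 405 nm (isosbestic
#' reference) fluorescence over the trial schedule in `cfg`, with known
#' ground truth. The signal channel is
#' `bleach + transients + motion + noise`; the reference carries the same
#' bleach and motion terms plus independent noise but no transients, so
#' subtracting the bleach-corrected reference cancels motion exactly.
#' Transient event times are Poisson with a state-dependent rate read off
#' the hypnogram (mapped through the true clock relation); the transient
#' kernel is a difference of exponentials scaled to peak amplitude
#' `transient_amp_z * noise_sd`. A 1 s TTL pulse is emitted every
#' `ttl_period_s` on the photometry clock.
#'
#' @param cfg A [synth_config()].
#' @param hyp A hypnogram on the EEG clock covering the trial schedule
#'   (after mapping by the true clock offset/drift).
#' @return A list with `session` (tibble `time_s`, `sig465`, `ref405`,
#'   `ttl`; attributes `fs`, `ttl_onsets_s`, `trial_windows`) and `truth`
#'   (transient onset times per trial, kernel peak lag, motion times, bleach
#'   parameters, the true clock map).
#' @examples
#' cfg <- synth_config(seed = 3, n_trials = 1, trial_on_s = 120)
#' hyp <- generate_hypnogram(cfg, 120)
#' ses <- generate_photometry(cfg, hyp)
#' names(ses)
#' @export
generate_photometry <- function(cfg, hyp) {
  stopifnot(inherits(cfg, "synth_config"), inherits(hyp, "hypnogram"))
  fs <- cfg$photometry_fs_hz
  dur <- session_duration_s(cfg)
  drift <- 1 + cfg$clock_drift_ppm * 1e-6
  if (hyp_end_s(hyp) + 1e-9 < cfg$clock_offset_s + drift * dur)
    stop("hypnogram does not cover the trial schedule", call. = FALSE)

  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  tw <- trial_windows(cfg)

  withr_seed(cfg$seed, "photometry", {
    bleach <- cfg$bleach_amp * exp(-t / cfg$bleach_tau_s) + cfg$bleach_offset

    # state-dependent Poisson transient times by thinning a homogeneous train
    state_at_phot <- hyp_state_at(hyp, cfg$clock_offset_s + drift * t)
    rate_hz <- cfg$transient_rate_per_min / 60
    max_rate <- max(rate_hz)
    ev <- numeric(0)
    if (max_rate > 0) {
      n_cand <- stats::rpois(1, max_rate * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      st <- hyp_state_at(hyp, cfg$clock_offset_s + drift * cand)
      keep_p <- ifelse(is.na(st) | st == "ARTIFACT", 0,
                       rate_hz[st] / max_rate)
      ev <- cand[stats::runif(length(cand)) < keep_p]
    }
    amp <- cfg$transient_amp_z * cfg$noise_sd
    ker <- transient_kernel(cfg, fs)
    transients <- add_events(numeric(n), ev, fs, amp * ker$y)

    # shared biphasic motion pulses (one sine cycle, 0.4 s)
    n_mot <- stats::rpois(1, cfg$motion_rate_per_min / 60 * dur)
    mot_times <- sort(stats::runif(n_mot, 0, dur - 0.4))
    mot_pulse <- cfg$motion_amp * sin(2 * pi * seq(0, 1, by = 1 / (0.4 * fs)))
    motion <- add_events(numeric(n), mot_times, fs, mot_pulse)

    sig <- bleach + transients + motion + stats::rnorm(n, 0, cfg$noise_sd)
    ref <- bleach + motion + stats::rnorm(n, 0, cfg$noise_sd)

    ttl_onsets <- seq(0, dur - cfg$ttl_width_s, by = cfg$ttl_period_s)
    ttl <- pulse_train(t, ttl_onsets, cfg$ttl_width_s)

    session <- tibble::tibble(time_s = t, sig465 = sig, ref405 = ref, ttl = ttl)
    attr(session, "fs") <- fs
    attr(session, "ttl_onsets_s") <- ttl_onsets
    attr(session, "trial_windows") <- tw
    class(session) <- c("photometry_session", class(session))

    truth <- list(
      transient_times_s = lapply(seq_len(nrow(tw)), function(i)
        ev[ev >= tw$start_s[i] & ev < tw$end_s[i]]),
      transient_times_all_s = ev,
      kernel_peak_lag_s = ker$peak_lag_s,
      motion_times_s = mot_times,
      bleach_params = c(amp = cfg$bleach_amp, tau = cfg$bleach_tau_s,
                        offset = cfg$bleach_offset),
      clock_map_true = c(offset_s = cfg$clock_offset_s,
                         drift_ppm = cfg$clock_drift_ppm)
    )
    list(session = session, truth = truth)
  })
}

# difference-of-exponentials kernel sampled at fs, scaled to unit peak;
# truncated where the tail falls below 1e-3 of peak
transient_kernel <- function(cfg, fs) {
  r <- cfg$transient_rise_s
  d <- cfg$transient_decay_s
  t_end <- d * log(1000)
  tk <- seq(0, t_end, by = 1 / fs)
  y <- exp(-tk / d) - exp(-tk / r)
  peak_lag <- log(d / r) * r * d / (d - r)
  y <- y / (exp(-peak_lag / d) - exp(-peak_lag / r))
  list(y = y, peak_lag_s = peak_lag)
}

# add copies of `pulse` starting at `times` (s) into x (sampled at fs)
add_events <- function(x, times, fs, pulse) {
  if (!length(times) || !length(pulse)) return(x)
  np <- length(pulse)
  n <- length(x)
  for (tt in times) {
    i0 <- as.integer(round(tt * fs)) + 1L
    idx <- i0:min(i0 + np - 1L, n)
    if (i0 <= n) x[idx] <- x[idx] + pulse[seq_along(idx)]
  }
  x
}

# binary pulse train sampled on t (1 during [onset, onset + width))
pulse_train <- function(t, onsets, width_s) {
  y <- numeric(length(t))
  fs <- 1 / (t[2] - t[1])
  for (o in onsets) {
    i0 <- as.integer(round((o - t[1]) * fs)) + 1L
    i1 <- as.integer(round((o + width_s - t[1]) * fs))
    i0 <- max(i0, 1L); i1 <- min(i1, length(t))
    if (i0 <= i1) y[i0:i1] <- 1
  }
  y
}

session_fs <- function(session) attr(session, "fs") %||% stop("session lacks fs")
session_trials <- function(session) {
  tw <- attr(session, "trial_windows")
  if (is.null(tw)) {
    tw <- tibble::tibble(trial = 1L, start_s = session$time_s[1],
                         end_s = session$time_s[nrow(session)] + 1 / session_fs(session))
  }
  tw
}
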