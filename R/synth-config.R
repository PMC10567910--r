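#' Configuration for the synthetic recording generator
#'
#' Bundles every parameter of the synthetic multimodal session: the sleep-wake
#' state process, photometry transient/bleach/motion model, EEG/EMG band
#' weights, the trial and TTL schedule, and the two acquisition clocks.
#' Defaults reproduce a typical recording session: six 15-min photometry
#' trials separated by 15-min breaks, 10-s scoring epochs, a 1-s TTL pulse
#' every 3 min shared between the photometry and EEG systems, photometry
#' sampled at 120 Hz (post-demodulation) and EEG/EMG at 400 Hz.
#'
#' @param seed Integer seed; the whole session is reproducible given the
#'   config (including this seed).
#' @param epoch_s Scoring epoch length in seconds (default 10).
#' @param state_mean_dwell_s Named list/vector of mean dwell times (s) per
#'   state; dwell per visit is geometric on epochs with this mean.
#' @param transition_probs Row-stochastic named matrix of between-state
#'   transition probabilities with zero diagonal (rows: from, cols: to).
#' @param artifact_fraction Fraction of epochs relabelled ARTIFACT at random
#'   (default 0: clean hypnogram).
#' @param transient_rate_per_min Named vector of Ca2+ transient rates
#'   (events/min) per state.
#' @param transient_amp_z Transient amplitude as a multiple of `noise_sd`.
#' @param transient_rise_s,transient_decay_s Difference-of-exponentials
#'   kernel time constants (s); decay must exceed rise.
#' @param bleach_amp,bleach_tau_s,bleach_offset Photobleaching model
#'   `amp * exp(-t / tau) + offset` shared by both channels.
#' @param motion_rate_per_min Rate of shared motion artifacts (events/min).
#' @param motion_amp Motion pulse amplitude (a.u.), identical on both
#'   channels so reference subtraction cancels it.
#' @param noise_sd Additive white measurement noise sd (a.u.), independent
#'   between channels.
#' @param photometry_fs_hz Photometry sampling rate (Hz, default 120; must
#'   exceed 10 Hz so the final 5 Hz low-pass is below Nyquist).
#' @param eeg_fs_hz EEG/EMG sampling rate; fixed at 400 Hz.
#' @param trial_on_s,trial_off_s,n_trials Photometry trial schedule:
#'   `n_trials` recordings of `trial_on_s` seconds separated by
#'   `trial_off_s` breaks.
#' @param ttl_period_s,ttl_width_s Synchronization pulse period and width (s).
#' @param clock_offset_s,clock_drift_ppm True EEG-clock offset (s) and drift
#'   (parts per million) relative to the photometry clock.
#' @param emg_level Named vector of EMG envelope scales per state
#'   (WAKE >> NREM > REM).
#'
#' @return A `synth_config` list, validated.
#' @examples
#' cfg <- synth_config(seed = 1, n_trials = 2, trial_on_s = 300, trial_off_s = 300)
#' cfg$ttl_period_s
#' @export
synth_config <- function(seed = 1L,
                         epoch_s = 10,
                         state_mean_dwell_s = c(WAKE = 120, NREM = 120, REM = 60),
                         transition_probs = default_transition_probs(),
                         artifact_fraction = 0,
                         transient_rate_per_min = c(WAKE = 10, NREM = 1, REM = 5),
                         transient_amp_z = 5,
                         transient_rise_s = 0.2,
                         transient_decay_s = 1.5,
                         bleach_amp = 5,
                         bleach_tau_s = 300,
                         bleach_offset = 2,
                         motion_rate_per_min = 0.5,
                         motion_amp = 1,
                         noise_sd = 0.05,
                         photometry_fs_hz = 120,
                         eeg_fs_hz = 400,
                         trial_on_s = 900,
                         trial_off_s = 900,
                         n_trials = 6,
                         ttl_period_s = 180,
                         ttl_width_s = 1,
                         clock_offset_s = 0,
                         clock_drift_ppm = 0,
                         emg_level = c(WAKE = 3, NREM = 1, REM = 0.3)) {
  cfg <- list(
    seed = as.integer(seed), epoch_s = epoch_s,
    state_mean_dwell_s = state_mean_dwell_s,
    transition_probs = transition_probs,
    artifact_fraction = artifact_fraction,
    transient_rate_per_min = transient_rate_per_min,
    transient_amp_z = transient_amp_z,
    transient_rise_s = transient_rise_s,
    transient_decay_s = transient_decay_s,
    bleach_amp = bleach_amp, bleach_tau_s = bleach_tau_s,
    bleach_offset = bleach_offset,
    motion_rate_per_min = motion_rate_per_min, motion_amp = motion_amp,
    noise_sd = noise_sd,
    photometry_fs_hz = photometry_fs_hz, eeg_fs_hz = eeg_fs_hz,
    trial_on_s = trial_on_s, trial_off_s = trial_off_s,
    n_trials = as.integer(n_trials),
    ttl_period_s = ttl_period_s, ttl_width_s = ttl_width_s,
    clock_offset_s = clock_offset_s, clock_drift_ppm = clock_drift_ppm,
    emg_level = emg_level
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  seed:", x$seed, " epoch:", x$epoch_s, "s\n")
  cat("  trials:", x$n_trials, "x", x$trial_on_s, "s on /", x$trial_off_s, "s off\n")
  cat("  fs: photometry", x$photometry_fs_hz, "Hz, EEG", x$eeg_fs_hz, "Hz\n")
  cat("  transient rates (/min):",
      paste(names(x$transient_rate_per_min), x$transient_rate_per_min,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Default sleep-wake transition matrix
#'
#' WAKE alternates with NREM; NREM may move to WAKE or REM; REM always ends
#' in WAKE (the physiological ordering in rodents, where REM is entered from
#' NREM only).
#' @return A 3x3 row-stochastic matrix with zero diagonal.
#' @export
default_transition_probs <- function() {
  m <- matrix(0, 3, 3, dimnames = list(c("WAKE", "NREM", "REM"),
                                       c("WAKE", "NREM", "REM")))
  m["WAKE", "NREM"] <- 1
  m["NREM", c("WAKE", "REM")] <- c(0.65, 0.35)
  m["REM", "WAKE"] <- 1
  m
}

sleep_states <- function() c("WAKE", "NREM", "REM")

validate_synth_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  pos <- c("epoch_s", "photometry_fs_hz", "eeg_fs_hz", "trial_on_s",
           "ttl_period_s", "ttl_width_s", "transient_rise_s",
           "transient_decay_s", "bleach_tau_s")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("synth_config: `", f, "` must be a positive finite number",
           call. = FALSE)
  }
  nonneg <- c("artifact_fraction", "motion_rate_per_min", "motion_amp",
              "noise_sd", "transient_amp_z", "bleach_amp", "trial_off_s",
              "n_trials")
  for (f in nonneg) {
    if (any(!is.finite(cfg[[f]]) | cfg[[f]] < 0))
      stop("synth_config: `", f, "` must be non-negative", call. = FALSE)
  }
  if (any(cfg$state_mean_dwell_s <= 0) ||
      !all(sleep_states() %in% names(cfg$state_mean_dwell_s)))
    stop("synth_config: `state_mean_dwell_s` needs positive WAKE/NREM/REM entries",
         call. = FALSE)
  if (any(cfg$transient_rate_per_min < 0) ||
      !all(sleep_states() %in% names(cfg$transient_rate_per_min)))
    stop("synth_config: `transient_rate_per_min` needs WAKE/NREM/REM entries",
         call. = FALSE)
  if (cfg$photometry_fs_hz <= 10)
    stop("synth_config: photometry_fs_hz must exceed 10 Hz (Nyquist margin for the 5 Hz low-pass)",
         call. = FALSE)
  if (cfg$eeg_fs_hz != 400)
    stop("synth_config: eeg_fs_hz is fixed at 400 Hz", call. = FALSE)
  if (cfg$transient_decay_s <= cfg$transient_rise_s)
    stop("synth_config: transient_decay_s must exceed transient_rise_s",
         call. = FALSE)
  P <- cfg$transition_probs
  st <- sleep_states()
  if (!all(st %in% rownames(P)) || !all(st %in% colnames(P)))
    stop("synth_config: transition_probs must have WAKE/NREM/REM rows and columns",
         call. = FALSE)
  P <- P[st, st]
  if (any(abs(diag(P)) > 1e-12))
    stop("synth_config: transition_probs diagonal must be zero (dwell is explicit)",
         call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("synth_config: transition_probs rows must be non-negative and sum to 1",
         call. = FALSE)
  check_reachability(P)
  cfg$transition_probs <- P
  cfg
}

# every state must be reachable from every other, else dwell statistics are
# degenerate; simple breadth-first closure over the support of P
check_reachability <- function(P) {
  n <- nrow(P)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- which(colSums(P[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen))
      stop("synth_config: state `",
           paste(rownames(P)[!seen], collapse = ","),
           "` unreachable from `", rownames(P)[s], "`", call. = FALSE)
  }
  invisible(TRUE)
}

# total session span (s) covered by the trial schedule
session_duration_s <- function(cfg) {
  cfg$n_trials * cfg$trial_on_s + max(cfg$n_trials - 1, 0) * cfg$trial_off_s
}

# trial windows (start, end) on the photometry clock
trial_windows <- function(cfg) {
  start <- (seq_len(cfg$n_trials) - 1) * (cfg$trial_on_s + cfg$trial_off_s)
  tibble::tibble(trial = seq_len(cfg$n_trials),
                 start_s = start, end_s = start + cfg$trial_on_s)
}
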