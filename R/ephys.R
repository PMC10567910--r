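#' Detect spikes by threshold crossing
#'
#' Upward crossings of `threshold_mv` are spike times; crossings within
#' the refractory window after an accepted spike are ignored.
#'
#' @param vm Membrane potential (mV).
#' @param fs Sampling rate (Hz), at least 1 kHz.
#' @param threshold_mv Detection threshold (default -20 mV, well above
#'   subthreshold fluctuations and well below rendered spike peaks).
#' @param refractory_s Minimum inter-spike interval (default 2 ms).
#' @return Strictly increasing spike times (s).
#' @export
detect_spikes <- function(vm, fs, threshold_mv = -20, refractory_s = 0.002) {
  stopifnot(fs >= 1000)
  if (!all(is.finite(vm))) stop("non-finite samples in input", call. = FALSE)
  up <- which(vm[-1] >= threshold_mv & vm[-length(vm)] < threshold_mv) + 1L
  if (!length(up)) return(numeric(0))
  t <- (up - 1) / fs
  keep <- numeric(0)
  last <- -Inf
  for (tt in t) {
    if (tt - last >= refractory_s) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Spontaneous firing rate from the baseline window
#'
#' Spike count over the pre-stimulation baseline divided by its duration.
#' Baselines shorter than 30 s are rejected: spontaneous rates are only
#' meaningful over a sufficiently long unstimulated stretch.
#'
#' @param rec A `patch_recording` tibble (`time_s`, `vm_mv`) with `fs` and
#'   `baseline_duration_s` attributes.
#' @param min_baseline_s Minimum acceptable baseline (s, default 30).
#' @param ... Passed to [detect_spikes()].
#' @return Rate in Hz.
#' @export
spontaneous_rate <- function(rec, min_baseline_s = 30, ...) {
  fs <- attr(rec, "fs")
  b <- attr(rec, "baseline_duration_s")
  if (is.null(b) || b < min_baseline_s)
    stop("baseline shorter than ", min_baseline_s,
         " s: spontaneous rate rejected", call. = FALSE)
  vm <- rec$vm_mv[rec$time_s < b]
  length(detect_spikes(vm, fs, ...)) / b
}

#' Evoked firing: the f-I curve
#'
#' Firing rate per current step: spikes whose times fall inside
#' `[step_start, step_start + step_duration)` divided by the step
#' duration, one row per sweep, ordered by injected current.
#'
#' @param rec A `patch_recording` with a `sweeps` attribute
#'   (`current_pA`, `step_start_s`, `step_duration_s`).
#' @param ... Passed to [detect_spikes()].
#' @return An `fi_curve` tibble: `current_pA`, `n_spikes`, `rate_hz`.
#' @export
f_i_curve <- function(rec, ...) {
  sw <- attr(rec, "sweeps")
  if (is.null(sw) || !nrow(sw)) stop("recording has no sweeps", call. = FALSE)
  sw <- sw[order(sw$step_start_s), ]
  ends <- sw$step_start_s + sw$step_duration_s
  if (any(sw$step_start_s[-1] < ends[-nrow(sw)]))
    stop("overlapping current steps in protocol", call. = FALSE)
  spikes <- detect_spikes(rec$vm_mv, attr(rec, "fs"), ...)
  out <- tibble::tibble(
    current_pA = sw$current_pA,
    n_spikes = vapply(seq_len(nrow(sw)), function(k)
      sum(spikes >= sw$step_start_s[k] & spikes < ends[k]), 0L),
  )
  out$rate_hz <- out$n_spikes / sw$step_duration_s
  out <- out[order(out$current_pA), ]
  class(out) <- c("fi_curve", class(out))
  out
}

#' Restrict a cell population to spontaneously firing cells
#'
#' Keeps the cells whose spontaneous (baseline) firing rate is positive
#' and reports the retained fraction. Evoked-response analyses are
#' conventionally restricted to this subset.
#'
#' @param cells List of `patch_recording` objects (or of lists holding one
#'   under `$recording`).
#' @param ... Passed to [spontaneous_rate()].
#' @return List with `cells` (the retained subset), `rates_hz` (all
#'   cells), `retained` (logical), `fraction`.
#' @export
restrict_to_spontaneous <- function(cells, ...) {
  recs <- lapply(cells, function(c)
    if (inherits(c, "patch_recording")) c else c$recording)
  rates <- vapply(recs, spontaneous_rate, 0, ...)
  keep <- rates > 0
  list(cells = cells[keep], rates_hz = rates, retained = keep,
       fraction = mean(keep))
}
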