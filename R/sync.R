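#' Detect TTL pulse onsets
#'
#' Finds rising edges of synchronization pulses in a binary or analog TTL
#' channel. The threshold is half the channel maximum; only pulses at least
#' `min_width_s` wide (default 0.5 s, half the nominal 1 s pulse) are kept.
#'
#' @param x Numeric TTL trace.
#' @param fs Sampling rate (Hz), must exceed 2 Hz.
#' @param min_width_s Minimum above-threshold run length (s) for a pulse.
#' @return Strictly increasing numeric vector of onset times (s); empty if
#'   no pulses are found.
#' @examples
#' fs <- 100
#' x <- rep(0, 1000); x[101:200] <- 1
#' detect_ttl_onsets(x, fs)
#' @export
detect_ttl_onsets <- function(x, fs, min_width_s = 0.5) {
  stopifnot(fs > 2)
  if (!length(x) || max(x) <= 0) return(numeric(0))
  thr <- max(x) / 2
  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width_s * fs
  sort((starts[keep] - 1L) / fs)
}

#' Fit an affine clock map between the photometry and EEG timebases
#'
#' Matches the two TTL onset trains (greedy nearest neighbour after a
#' coarse offset by the first pulses) and fits the least-squares line
#' `eeg_t = offset + drift * phot_t`. With exactly two matched pulses the
#' line is exact; drift must land in (0.9, 1.1) for a sane recording pair.
#'
#' @param onsets_photometry,onsets_eeg Onset times (s) on each clock.
#' @return A `clock_map` object with `offset_s`, `drift`, `residual_rms_s`
#'   and `n_matched`. Use [map_time()] / [unmap_time()] to convert times.
#' @examples
#' m <- fit_clock_map(c(0, 180, 360), c(7, 187, 367))
#' m$offset_s
#' @export
fit_clock_map <- function(onsets_photometry, onsets_eeg) {
  np <- length(onsets_photometry); ne <- length(onsets_eeg)
  if (np < 2 || ne < 2)
    stop("clock alignment needs at least 2 TTL pulses in each train",
         call. = FALSE)
  if (abs(np - ne) > 1)
    stop("TTL pulse counts differ by more than 1 (", np, " vs ", ne,
         "): cannot align", call. = FALSE)
  coarse <- onsets_eeg[1] - onsets_photometry[1]
  # greedy nearest-neighbour matching; ties broken by the earlier index
  used <- rep(FALSE, ne)
  match_idx <- integer(np)
  for (i in seq_len(np)) {
    d <- abs(onsets_eeg - (onsets_photometry[i] + coarse))
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) { match_idx[i] <- NA_integer_; next }
    match_idx[i] <- j
    used[j] <- TRUE
  }
  ok <- !is.na(match_idx)
  xp <- onsets_photometry[ok]
  xe <- onsets_eeg[match_idx[ok]]
  if (length(xp) < 2)
    stop("fewer than 2 matched TTL pulses", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, xp), xe)
  offset <- unname(fit$coefficients[1])
  drift <- unname(fit$coefficients[2])
  if (!is.finite(drift) || drift <= 0.9 || drift >= 1.1)
    stop("fitted clock drift ", format(drift),
         " outside the plausible (0.9, 1.1) range", call. = FALSE)
  structure(list(offset_s = offset, drift = drift,
                 residual_rms_s = sqrt(mean(fit$residuals^2)),
                 n_matched = length(xp)),
            class = "clock_map")
}

#' Identity clock map (both timebases already aligned)
#' @return A `clock_map` with zero offset and unit drift.
#' @export
identity_clock_map <- function() {
  structure(list(offset_s = 0, drift = 1, residual_rms_s = 0,
                 n_matched = NA_integer_),
            class = "clock_map")
}

#' Convert photometry-clock times to the EEG clock (and back)
#'
#' @param map A `clock_map` from [fit_clock_map()].
#' @param t_s Times (s) on the photometry clock (for [map_time()]) or the
#'   EEG clock (for [unmap_time()]).
#' @return Mapped times (s).
#' @export
map_time <- function(map, t_s) {
  stopifnot(inherits(map, "clock_map"))
  map$offset_s + map$drift * t_s
}

#' @rdname map_time
#' @export
unmap_time <- function(map, t_s) {
  stopifnot(inherits(map, "clock_map"))
  (t_s - map$offset_s) / map$drift
}

#' @export
print.clock_map <- function(x, ...) {
  cat("<clock_map> eeg_t = ", format(x$offset_s), " + ", format(x$drift),
      " * phot_t  (residual RMS ", format(x$residual_rms_s), " s, ",
      x$n_matched, " pulses)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy clock_map
#' @export
tidy.clock_map <- function(x, ...) {
  tibble::tibble(term = c("offset_s", "drift"),
                 estimate = c(x$offset_s, x$drift))
}

#' @method glance clock_map
#' @export
glance.clock_map <- function(x, ...) {
  tibble::tibble(offset_s = x$offset_s, drift = x$drift,
                 drift_ppm = (x$drift - 1) * 1e6,
                 residual_rms_s = x$residual_rms_s, n_matched = x$n_matched)
}
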