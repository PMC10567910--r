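#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass; the cutoff
#' is the -3 dB point. Used at 0.1 Hz to isolate the photobleaching trend
#' and at 5 Hz for the final z-score smoothing. For cutoffs below 1/500 of
#' the sampling rate the filter is applied on a decimated copy of the trace
#' and interpolated back, which keeps the recursion numerically stable at
#' extreme normalized cutoffs.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz -3 dB cutoff (Hz), in (0, fs/2).
#' @param order Filter order (default 4).
#' @return Filtered trace, same length as `x`.
#' @examples
#' lowpass_filter(rep(1, 100), fs = 100, cutoff_hz = 5)
#' @export
lowpass_filter <- function(x, fs, cutoff_hz, order = 4) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples in input", call. = FALSE)
  w <- cutoff_hz / (fs / 2)
  if (w < 1 / 250) {
    # decimate so the normalized cutoff is ~1/50, filter, interpolate back
    dec <- max(1L, floor(fs / (cutoff_hz * 50)))
    idx <- seq(1L, length(x), by = dec)
    if (length(idx) >= 12) {
      xd <- x[idx]
      yd <- zerophase_filter(signal::butter(order, cutoff_hz / (fs / dec / 2)), xd)
      return(stats::approx(idx, yd, xout = seq_along(x), rule = 2)$y)
    }
  }
  zerophase_filter(signal::butter(order, w), x)
}

# forward-backward application of a signal::butter filter with simple
# edge padding (reflection) to limit transients
zerophase_filter <- function(flt, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(flt$b), length(flt$a)) * 10L)
  if (pad > 0) {
    xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
    y <- signal::filtfilt(flt, xp)
    y[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Fit an exponential photobleaching curve
#'
#' Least-squares fit of `A * exp(-t / tau) + C` to a (typically 0.1
#' Hz-low-passed) fluorescence trace. Starting values come from a
#' log-linear regression on the offset-subtracted trace; if the trace is
#' flat or rising (no decay to fit) the fit degenerates gracefully to
#' `A = 0, C = mean(x)`.
#'
#' @param x Numeric trace (a.u.), at least 10 samples, all finite.
#' @param time_s Sample times (s), same length.
#' @return A `bleach_fit` with `amplitude`, `tau_s`, `offset`, `rss` and a
#'   [predict][stats::predict] method.
#' @examples
#' t <- seq(0, 900, by = 1)
#' f <- fit_bleach(5 * exp(-t / 300) + 2, t)
#' round(c(f$amplitude, f$tau_s, f$offset), 2)
#' @export
fit_bleach <- function(x, time_s) {
  if (length(x) < 10) stop("need at least 10 samples to fit bleach", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(time_s)))
    stop("non-finite samples in input", call. = FALSE)
  span <- max(time_s) - min(time_s)
  flat <- function() new_bleach_fit(0, span, mean(x), sum((x - mean(x))^2))

  if (stats::sd(x) < 1e-12) return(flat())
  # overall decay direction; rising or flat traces get the degenerate fit
  slope <- stats::cov(time_s, x) / stats::var(time_s)
  if (slope >= 0) return(flat())

  t0 <- time_s - min(time_s)
  c0 <- min(x) - 0.05 * diff(range(x))
  w <- pmax(x - c0, 1e-9 * diff(range(x)))
  ll <- stats::lm.fit(cbind(1, t0), log(w))
  tau0 <- unname(-1 / ll$coefficients[2])
  a0 <- unname(exp(ll$coefficients[1]))
  if (!is.finite(tau0) || tau0 <= 0) { tau0 <- span / 3; a0 <- diff(range(x)) }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      x ~ A * exp(-t0 / tau) + C,
      start = list(A = a0, tau = tau0, C = c0),
      lower = c(A = 0, tau = 1e-6, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flat())
  p <- stats::coef(fit)
  # report in absolute time: A*exp(-(t - t_min)/tau) == A' * exp(-t/tau)
  new_bleach_fit(unname(p["A"]), unname(p["tau"]), unname(p["C"]),
                 sum(stats::resid(fit)^2), t_ref = min(time_s))
}

new_bleach_fit <- function(amplitude, tau_s, offset, rss, t_ref = 0) {
  structure(list(amplitude = amplitude, tau_s = tau_s, offset = offset,
                 rss = rss, t_ref_s = t_ref),
            class = "bleach_fit")
}

#' @export
predict.bleach_fit <- function(object, time_s, ...) {
  object$amplitude * exp(-(time_s - object$t_ref_s) / object$tau_s) +
    object$offset
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat("<bleach_fit> ", format(x$amplitude), " * exp(-t/", format(x$tau_s),
      " s) + ", format(x$offset), "  (rss ", format(x$rss), ")\n", sep = "")
  invisible(x)
}

#' @method tidy bleach_fit
#' @export
tidy.bleach_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "tau_s", "offset"),
                 estimate = c(x$amplitude, x$tau_s, x$offset))
}

#' @method glance bleach_fit
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, tau_s = x$tau_s,
                 offset = x$offset, rss = x$rss)
}

#' Photometry preprocessing chain
#'
#' Runs the full correction chain per trial window:
#' \enumerate{
#'   \item low-pass both channels at `bleach_lp_hz` (0.1 Hz) and fit the
#'     exponential bleaching curve to each;
#'   \item subtract each fitted curve from its raw channel;
#'   \item motion-correct by subtracting the bleach-corrected reference
#'     from the bleach-corrected signal;
#'   \item robust z-score: subtract the median and divide by the median
#'     absolute deviation (no normal-consistency constant by default);
#'   \item zero-phase low-pass the z-score at `final_lp_hz` (5 Hz).
#' }
#' Trials shorter than `min_trial_s` are skipped with a warning. If the
#' motion-corrected trace has exactly zero MAD (degenerate, e.g. identical
#' channels) the division is skipped and the trial flagged.
#'
#' @param session A photometry session tibble (`time_s`, `sig465`,
#'   `ref405`) with `fs` and `trial_windows` attributes, as produced by
#'   [generate_photometry()] or [read_photometry_csv()].
#' @param bleach_lp_hz Cutoff for the bleach-trend low-pass (default 0.1).
#' @param final_lp_hz Final smoothing cutoff (default 5).
#' @param mad_constant Multiplier applied to the raw median absolute
#'   deviation (default 1; 1.4826 gives the normal-consistent scale).
#' @param z_scope `"trial"` (default) computes the median/MAD per trial
#'   window; `"session"` pools all trials for one median/MAD.
#' @param scaled_reference If TRUE, the reference is least-squares scaled
#'   to the signal before subtraction instead of subtracted 1:1.
#' @param min_trial_s Minimum trial length (s) to process.
#' @return A `zscore_trace` tibble with `time_s`, `trial`, `z` (smoothed)
#'   and `z_unsmoothed` (after step 4, before step 5); attributes `fs` and
#'   `trial_windows`.
#' @export
preprocess_photometry <- function(session,
                                  bleach_lp_hz = 0.1, final_lp_hz = 5,
                                  mad_constant = 1,
                                  z_scope = c("trial", "session"),
                                  scaled_reference = FALSE,
                                  min_trial_s = 60) {
  z_scope <- match.arg(z_scope)
  fs <- session_fs(session)
  tw <- session_trials(session)
  pieces <- list()
  for (k in seq_len(nrow(tw))) {
    i <- which(session$time_s >= tw$start_s[k] - 1e-9 &
                 session$time_s < tw$end_s[k] - 1e-9)
    if (length(i) < min_trial_s * fs) {
      warning("trial ", tw$trial[k], " shorter than ", min_trial_s,
              " s: skipped", call. = FALSE)
      next
    }
    t <- session$time_s[i]
    detr_sig <- detrend_channel(session$sig465[i], t, fs, bleach_lp_hz)
    detr_ref <- detrend_channel(session$ref405[i], t, fs, bleach_lp_hz)
    if (scaled_reference) {
      beta <- sum(detr_sig * detr_ref) / max(sum(detr_ref^2), 1e-300)
      x <- detr_sig - beta * detr_ref
    } else {
      x <- detr_sig - detr_ref
    }
    pieces[[length(pieces) + 1]] <-
      tibble::tibble(time_s = t, trial = tw$trial[k], x = x)
  }
  if (!length(pieces)) stop("no processable trials in session", call. = FALSE)
  out <- dplyr::bind_rows(pieces)

  robust_z <- function(x) {
    med <- stats::median(x)
    s <- mad_constant * stats::median(abs(x - med))
    if (s == 0) x - med else (x - med) / s
  }
  if (z_scope == "session") {
    out$z_unsmoothed <- robust_z(out$x)
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$trial),
                         z_unsmoothed = robust_z(.data$x))
    out <- dplyr::ungroup(out)
  }
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$trial),
    z = lowpass_filter(.data$z_unsmoothed, fs, final_lp_hz)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::select(out, "time_s", "trial", "z", "z_unsmoothed")
  attr(out, "fs") <- fs
  attr(out, "trial_windows") <- tw[tw$trial %in% unique(out$trial), ]
  class(out) <- c("zscore_trace", class(out))
  out
}

# low-pass at the bleach cutoff, fit the exponential, subtract from RAW
detrend_channel <- function(raw, t, fs, bleach_lp_hz) {
  lp <- lowpass_filter(raw, fs, bleach_lp_hz)
  fit <- fit_bleach(lp, t)
  raw - predict(fit, t)
}

trace_fs <- function(z) attr(z, "fs") %||% stop("trace lacks fs attribute")
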