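#' Find consolidated sleep/wake state transitions
#'
#' Scans the hypnogram for boundaries of the four tracked kinds
#' (NREM->WAKE, WAKE->NREM, NREM->REM, REM->WAKE) and keeps those flanked
#' by consolidated states: the `ceiling(consolidation_s / epoch_s)` epochs
#' before the boundary must all carry the source state and (by default)
#' the same number after it the target state, with no ARTIFACT epoch in
#' either flank. A 15 s window on a 10 s grid is thus enforced as 2 full
#' epochs (20 s) per side.
#'
#' @param hyp A hypnogram.
#' @param consolidation_s Required consolidated time per side (s).
#' @param both_sides Require purity on both sides (default); if FALSE only
#'   the pre-transition flank is checked.
#' @param keep_all Return all candidate boundaries with their flank flags
#'   instead of only the retained ones.
#' @return Tibble `kind`, `time_s` (epoch boundary on the EEG clock),
#'   `pre_ok`, `post_ok`.
#' @export
find_transitions <- function(hyp, consolidation_s = 15, both_sides = TRUE,
                             keep_all = FALSE) {
  ep <- hyp_epoch_s(hyp)
  k <- as.integer(ceiling(consolidation_s / ep))
  lab <- hyp$state
  n <- length(lab)
  kinds <- c("NREM->WAKE", "WAKE->NREM", "NREM->REM", "REM->WAKE")
  res <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      a <- lab[i]; b <- lab[i + 1]
      if (a == b) next
      kind <- paste0(a, "->", b)
      if (!kind %in% kinds) next
      pre_ok <- i >= k && all(lab[(i - k + 1):i] == a)
      post_ok <- i + k <= n && all(lab[(i + 1):(i + k)] == b)
      res[[length(res) + 1]] <- tibble::tibble(
        kind = kind, time_s = hyp$start_s[i + 1],
        pre_ok = pre_ok, post_ok = post_ok
      )
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(kind = character(), time_s = numeric(),
                   pre_ok = logical(), post_ok = logical())
  if (!keep_all)
    out <- out[out$pre_ok & (out$post_ok | !both_sides), ]
  out
}

#' Transition-triggered photometry traces
#'
#' Extracts the z-scored fluorescence in a window around each state
#' transition (default 15 s on each side), resampled on a common grid
#' centred at the boundary. Each event's trace is normalized to its own
#' within-window maximum (rows whose maximum is not positive are left
#' unnormalized and flagged); the mean and SEM across events are computed
#' on the normalized rows. Events whose windows leave the recorded trial
#' coverage are dropped and counted.
#'
#' @param z A `zscore_trace` from [preprocess_photometry()].
#' @param events Transition events from [find_transitions()] (times on the
#'   EEG clock), or a numeric vector of EEG-clock times.
#' @param map A `clock_map` relating the two timebases.
#' @param window_s Length-2 vector `(pre, post)` in seconds.
#' @return A `transition_trace_set`: list with `time_rel_s`, `traces`
#'   (events x samples, max-normalized), `raw_traces`, `kind`, `mean_trace`,
#'   `sem_trace`, `n_events`, `n_dropped`, `unnormalized` (row flags).
#'   Empty event sets yield an error.
#' @export
transition_triggered <- function(z, events, map = identity_clock_map(),
                                 window_s = c(15, 15)) {
  fs <- trace_fs(z)
  if (is.numeric(events)) events <- tibble::tibble(kind = NA_character_,
                                                   time_s = events)
  if (!"trial" %in% names(z)) z$trial <- 1L
  rel <- seq(-window_s[1], window_s[2], by = 1 / fs)
  trials <- unique(z$trial)
  spans <- lapply(trials, function(tr) range(z$time_s[z$trial == tr]))
  names(spans) <- as.character(trials)

  rows <- list(); kinds <- character(0); dropped <- 0L
  for (e in seq_len(nrow(events))) {
    t0 <- unmap_time(map, events$time_s[e])  # photometry clock
    win <- t0 + range(rel)
    tr <- NULL
    for (trn in trials) {
      sp <- spans[[as.character(trn)]]
      if (win[1] >= sp[1] - 1e-9 && win[2] <= sp[2] + 1e-9) { tr <- trn; break }
    }
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    d <- z[z$trial == tr, ]
    rows[[length(rows) + 1]] <- stats::approx(d$time_s, d$z, xout = t0 + rel,
                                              rule = 2)$y
    kinds <- c(kinds, events$kind[e])
  }
  if (!length(rows))
    stop("no transition events with a full window inside the recording",
         call. = FALSE)
  raw <- do.call(rbind, rows)
  row_max <- apply(raw, 1, max)
  unnorm <- row_max <= 0
  traces <- raw
  traces[!unnorm, ] <- raw[!unnorm, , drop = FALSE] / row_max[!unnorm]
  mean_trace <- colMeans(traces)
  sem_trace <- if (nrow(traces) > 1)
    apply(traces, 2, stats::sd) / sqrt(nrow(traces)) else
      rep(NA_real_, ncol(traces))
  structure(list(time_rel_s = rel, traces = traces, raw_traces = raw,
                 kind = kinds, mean_trace = mean_trace,
                 sem_trace = sem_trace, n_events = nrow(traces),
                 n_dropped = dropped, unnormalized = unnorm),
            class = "transition_trace_set")
}

#' @export
print.transition_trace_set <- function(x, ...) {
  cat("<transition_trace_set> ", x$n_events, " events (",
      x$n_dropped, " dropped), window ", -x$time_rel_s[1], "/",
      x$time_rel_s[length(x$time_rel_s)], " s\n", sep = "")
  invisible(x)
}

#' @method tidy transition_trace_set
#' @export
tidy.transition_trace_set <- function(x, ...) {
  tibble::tibble(time_rel_s = x$time_rel_s, mean = x$mean_trace,
                 sem = x$sem_trace)
}
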