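#' Read and write pipeline artifacts as plain CSV/JSON
#'
#' Photometry sessions, hypnograms and z-traces are exchanged as plain
#' columnar CSV; session metadata that cannot live in columns (sampling
#' rate, trial windows) goes into a JSON sidecar written next to the CSV
#' (`<path>.meta.json`).
#'
#' @param session A photometry session tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_photometry_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  meta <- list(fs = session_fs(session),
               ttl_onsets_s = attr(session, "ttl_onsets_s"),
               trial_windows = as.data.frame(session_trials(session)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_photometry_csv
#' @export
read_photometry_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    fs <- meta$fs
    tw <- tibble::as_tibble(meta$trial_windows)
    ttl <- meta$ttl_onsets_s
  } else {
    fs <- 1 / stats::median(diff(d$time_s))
    tw <- NULL
    ttl <- if ("ttl" %in% names(d)) detect_ttl_onsets(d$ttl, fs) else numeric(0)
  }
  attr(d, "fs") <- fs
  attr(d, "ttl_onsets_s") <- ttl
  if (!is.null(tw)) attr(d, "trial_windows") <- tw
  class(d) <- c("photometry_session", class(d))
  d
}

#' Read/write a hypnogram CSV (epoch_index, label)
#'
#' @param hyp A hypnogram tibble.
#' @param path CSV path.
#' @param epoch_s,t0_s Epoch length and origin used when reading a file
#'   without a `start_s` column.
#' @return The path (write) or a hypnogram tibble (read).
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(
    data.frame(epoch_index = hyp$epoch, label = hyp$state,
               start_s = hyp$start_s),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path, epoch_s = 10, t0_s = 0) {
  d <- utils::read.csv(path)
  if ("start_s" %in% names(d) && nrow(d) > 1) {
    epoch_s <- d$start_s[2] - d$start_s[1]
    t0_s <- d$start_s[1]
  }
  new_hypnogram(d$label, epoch_s = epoch_s, t0_s = t0_s)
}

#' Run the full synthetic multimodal pipeline from a config file
#'
#' One JSON config file drives generation and analysis end to end:
#' synthetic hypnogram, photometry and EEG/EMG are generated, the two
#' timebases are aligned from the shared TTL pulses, the photometry chain
#' is run, transients are detected and summarized per state, consolidated
#' transitions are extracted and averaged, and sleep summaries (bouts,
#' binned state percentages, Welch PSD, spectrogram) are computed. All
#' artifacts are written to `out_dir` as CSV (analysis outputs) and JSON
#' (clock map, ground truth, config echo); identical config gives
#' identical files.
#'
#' The config holds any [synth_config()] argument plus optional
#' `detect = list(min_width_s, min_prominence)` and
#' `psd = list(nfft, max_freq_hz)` blocks.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  detect_opts <- config$detect %||% list()
  psd_opts <- config$psd %||% list()
  config$detect <- NULL
  config$psd <- NULL
  if (!is.null(config$transition_probs))
    config$transition_probs <- as.matrix(config$transition_probs)
  cfg <- do.call(synth_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  # --- generate ---
  dur <- session_duration_s(cfg)
  drift <- 1 + cfg$clock_drift_ppm * 1e-6
  hyp_dur <- (ceiling((cfg$clock_offset_s + drift * dur) / cfg$epoch_s) + 1) *
    cfg$epoch_s
  hyp <- generate_hypnogram(cfg, hyp_dur)
  phot <- generate_photometry(cfg, hyp)
  eeg <- generate_eeg_emg(cfg, hyp)
  write_hypnogram_csv(hyp, p("hypnogram.csv"))
  write_photometry_csv(phot$session, p("photometry.csv"))
  jsonlite::write_json(
    lapply(phot$truth, function(x) if (is.list(x)) lapply(x, as.numeric) else x),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)

  # --- synchronize ---
  onsets_p <- detect_ttl_onsets(phot$session$ttl, session_fs(phot$session))
  onsets_e <- detect_ttl_onsets(eeg$ttl, attr(eeg, "fs"))
  cmap <- fit_clock_map(onsets_p, onsets_e)
  jsonlite::write_json(unclass(cmap)[c("offset_s", "drift", "residual_rms_s")],
                       p("clock_map.json"), auto_unbox = TRUE, digits = NA)

  # --- photometry chain ---
  z <- preprocess_photometry(phot$session)
  utils::write.csv(as.data.frame(z), p("ztrace.csv"), row.names = FALSE)
  ts <- detect_transients(z,
                          min_width_s = detect_opts$min_width_s %||% 0.08,
                          min_prominence = detect_opts$min_prominence %||% 0.1)
  utils::write.csv(as.data.frame(ts), p("transients.csv"), row.names = FALSE)
  rates <- transient_rate_by_state(ts, hyp, cmap)
  proms <- transient_prominence_by_state(ts, hyp, cmap)
  zstate <- zscore_by_state(z, hyp, cmap)
  utils::write.csv(as.data.frame(
    dplyr::left_join(dplyr::left_join(rates, proms, by = c("state", "n")),
                     zstate, by = "state")),
    p("state_summary.csv"), row.names = FALSE)

  # --- transitions ---
  ev <- find_transitions(hyp)
  utils::write.csv(as.data.frame(ev), p("transitions.csv"), row.names = FALSE)
  tr_means <- list()
  for (k in unique(ev$kind)) {
    tt <- tryCatch(transition_triggered(z, ev[ev$kind == k, ], cmap),
                   error = function(e) NULL)
    if (!is.null(tt))
      tr_means[[k]] <- dplyr::mutate(tidy(tt), kind = k, n = tt$n_events)
  }
  if (length(tr_means))
    utils::write.csv(as.data.frame(dplyr::bind_rows(tr_means)),
                     p("transition_traces.csv"), row.names = FALSE)

  # --- sleep summaries ---
  bouts <- find_bouts(hyp)
  utils::write.csv(as.data.frame(bouts), p("bouts.csv"), row.names = FALSE)
  pct <- dplyr::bind_rows(lapply(sleep_states(), function(s)
    dplyr::mutate(percent_state_binned(hyp, s, 3600), state = s)))
  utils::write.csv(as.data.frame(pct), p("percent_state.csv"),
                   row.names = FALSE)
  nfft <- psd_opts$nfft %||% 1024
  psd <- welch_psd(eeg$eeg, attr(eeg, "fs"), nfft = nfft)
  utils::write.csv(as.data.frame(psd), p("psd.csv"), row.names = FALSE)
  sg <- spectrogram_stft(eeg$eeg, attr(eeg, "fs"),
                         max_freq_hz = psd_opts$max_freq_hz %||% 20)
  utils::write.csv(as.data.frame(sg), p("spectrogram.csv"),
                   row.names = FALSE)

  invisible(list(cfg = cfg, hypnogram = hyp, photometry = phot, eeg = eeg,
                 clock_map = cmap, ztrace = z, transients = ts,
                 state_rates = rates, transitions = ev, bouts = bouts,
                 psd = psd, spectrogram = sg))
}
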