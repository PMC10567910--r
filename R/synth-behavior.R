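#' Simulate locomotor and acoustic-startle data
#'
#' Locomotor activity is a Poisson beam-break count per 10 s bin with a
#' day/night rate step (circadian-time hours 0-12 vs 12-24). Startle trials
#' are platform-voltage traces: baseline sensor noise, a damped response
#' burst in the 100 ms after the tone, and (in a configurable fraction of
#' trials) a pre-tone contamination burst that the exclusion rule should
#' catch.
#'
#' @param cfg A [synth_config()] (supplies the seed).
#' @param days Days of locomotor recording.
#' @param day_rate,night_rate Poisson mean counts per 10 s bin for CT0-12
#'   and CT12-24.
#' @param lights `"LD"` or `"DD"` bookkeeping label.
#' @param n_startle Number of startle trials (tones cycle through
#'   100/110/120 dB).
#' @param startle_fs_hz Platform sampling rate (Hz).
#' @param response_amp_mv Response-burst scale at 100 dB; amplitude grows
#'   linearly with tone level (x1, x2, x3 at 100/110/120 dB).
#' @param baseline_sd_mv Sensor noise sd (mV).
#' @param contamination_frac Fraction of trials given a pre-tone burst
#'   (10x baseline sd).
#' @return List with `locomotor` (tibble `bin`, `t_start_s`, `ct_h`,
#'   `counts`, `lights`; class `locomotor_series`) and `startle` (tibble
#'   `trial`, `tone_db`, `tone_onset_s`, `contaminated`, `trace` list-column;
#'   attribute `fs`).
#' @export
generate_behavior <- function(cfg, days = 1, day_rate = 1, night_rate = 3,
                              lights = c("DD", "LD"),
                              n_startle = 15, startle_fs_hz = 1000,
                              response_amp_mv = 0.5, baseline_sd_mv = 0.02,
                              contamination_frac = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  lights <- match.arg(lights)
  withr_seed(cfg$seed, "behavior", {
    bin_s <- 10
    n_bins <- as.integer(days * 24 * 3600 / bin_s)
    t_start <- (seq_len(n_bins) - 1) * bin_s
    ct_h <- (t_start / 3600) %% 24
    rate <- ifelse(ct_h < 12, day_rate, night_rate)
    loco <- tibble::tibble(
      bin = seq_len(n_bins), t_start_s = t_start, ct_h = ct_h,
      counts = stats::rpois(n_bins, rate), lights = lights
    )
    attr(loco, "bin_s") <- bin_s
    class(loco) <- c("locomotor_series", class(loco))

    fs <- startle_fs_hz
    tone_onset <- 0.2
    trial_len <- 0.4
    nt <- as.integer(round(trial_len * fs))
    tones <- rep(c(100, 110, 120), length.out = n_startle)
    contaminated <- stats::runif(n_startle) < contamination_frac
    tt <- (seq_len(nt) - 1) / fs
    resp_win <- tt > tone_onset & tt <= tone_onset + 0.1
    pre_win <- tt > tone_onset - 0.1 & tt <= tone_onset
    traces <- lapply(seq_len(n_startle), function(i) {
      x <- stats::rnorm(nt, 0, baseline_sd_mv)
      amp <- response_amp_mv * (tones[i] - 90) / 10
      if (amp > 0) {
        tr <- tt[resp_win] - tone_onset
        burst <- amp * exp(-tr / 0.03) * sin(2 * pi * 40 * tr)
        x[resp_win] <- x[resp_win] + burst
      }
      if (contaminated[i]) {
        tp <- tt[pre_win] - (tone_onset - 0.1)
        x[pre_win] <- x[pre_win] +
          10 * baseline_sd_mv * sin(2 * pi * 40 * tp)
      }
      x
    })
    startle <- tibble::tibble(
      trial = seq_len(n_startle), tone_db = tones,
      tone_onset_s = tone_onset, contaminated = contaminated,
      trace = traces
    )
    attr(startle, "fs") <- fs
    list(locomotor = loco, startle = startle)
  })
}
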