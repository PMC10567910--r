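test_that("hypnogram generation is deterministic and respects dwell forcing", {
  cfg <- synth_config(seed = 42)
  h1 <- generate_hypnogram(cfg, 600)
  h2 <- generate_hypnogram(cfg, 600)
  expect_identical(h1$state, h2$state)

  # effectively absorbing WAKE: enormous mean dwell
  cfg_w <- synth_config(seed = 1,
                        state_mean_dwell_s = c(WAKE = 1e7, NREM = 120, REM = 60))
  h <- generate_hypnogram(cfg_w, 60, init_state = "WAKE")
  expect_equal(h$state, rep("WAKE", 6))
})

test_that("unreachable transition matrices are rejected", {
  P <- matrix(0, 3, 3, dimnames = list(c("WAKE", "NREM", "REM"),
                                       c("WAKE", "NREM", "REM")))
  P["WAKE", "NREM"] <- 1
  P["NREM", "WAKE"] <- 1
  P["REM", "WAKE"] <- 1  # REM never entered
  expect_error(synth_config(transition_probs = P), "unreachable")
})

test_that("empirical mean dwell matches the geometric construction", {
  dwells <- c()
  for (seed in 1:50) {
    cfg <- synth_config(seed = seed,
                        state_mean_dwell_s = c(WAKE = 60, NREM = 60, REM = 60))
    h <- generate_hypnogram(cfg, 3 * 3600)
    r <- rle(h$state)
    dwells <- c(dwells, r$lengths[-length(r$lengths)] * 10)
  }
  expect_lt(abs(mean(dwells) - 60) / 60, 0.15)
})

test_that("photometry null construction gives identical channels", {
  cfg <- synth_config(seed = 3, n_trials = 1, trial_on_s = 120,
                      transient_rate_per_min = c(WAKE = 0, NREM = 0, REM = 0),
                      noise_sd = 0, motion_rate_per_min = 0)
  hyp <- generate_hypnogram(cfg, 120)
  ph <- generate_photometry(cfg, hyp)
  expect_equal(ph$session$sig465, ph$session$ref405)
  expect_length(ph$truth$transient_times_all_s, 0)
})

test_that("the reference channel carries no transient kernel energy", {
  cfg <- synth_config(seed = 6, n_trials = 1, trial_on_s = 300,
                      motion_rate_per_min = 0,
                      transient_rate_per_min = c(WAKE = 10, NREM = 5, REM = 5))
  hyp <- generate_hypnogram(cfg, 300)
  ph <- generate_photometry(cfg, hyp)
  t <- ph$session$time_s
  bleach <- cfg$bleach_amp * exp(-t / cfg$bleach_tau_s) + cfg$bleach_offset
  # regress each bleach-subtracted channel on the true transient component
  ker <- arousalkit:::transient_kernel(cfg, 120)
  x_tr <- arousalkit:::add_events(numeric(length(t)),
                                  ph$truth$transient_times_all_s, 120, ker$y)
  expect_gt(cor(ph$session$sig465 - bleach, x_tr), 0.8)
  expect_lt(abs(cor(ph$session$ref405 - bleach, x_tr)), 0.05)
})

test_that("transient counts follow Poisson statistics in an all-WAKE record", {
  hits <- 0
  n_seeds <- 20
  for (seed in 1:n_seeds) {
    cfg <- synth_config(seed = seed, n_trials = 1, trial_on_s = 900,
                        state_mean_dwell_s = c(WAKE = 1e7, NREM = 120, REM = 60),
                        transient_rate_per_min = c(WAKE = 10, NREM = 0, REM = 0))
    hyp <- generate_hypnogram(cfg, 900, init_state = "WAKE")
    ph <- generate_photometry(cfg, hyp)
    n_tr <- length(ph$truth$transient_times_all_s)
    if (abs(n_tr - 150) <= 3 * sqrt(150)) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_seeds))
})

test_that("ground-truth events lie inside the generated record", {
  cfg <- synth_config(seed = 9, n_trials = 2, trial_on_s = 300,
                      trial_off_s = 60, motion_rate_per_min = 2)
  dur <- 2 * 300 + 60
  hyp <- generate_hypnogram(cfg, 660)
  ph <- generate_photometry(cfg, hyp)
  ev <- ph$truth$transient_times_all_s
  expect_true(all(ev >= 0 & ev <= dur))
  expect_true(all(ph$truth$motion_times_s >= 0 & ph$truth$motion_times_s <= dur))
  # per-trial lists partition the events falling inside trial windows
  tw <- attr(ph$session, "trial_windows")
  for (i in seq_len(nrow(tw))) {
    expect_true(all(ph$truth$transient_times_s[[i]] >= tw$start_s[i] &
                      ph$truth$transient_times_s[[i]] < tw$end_s[i]))
  }
})

test_that("degenerate bleach amplitude is recovered as ~0", {
  cfg <- synth_config(seed = 5, n_trials = 1, trial_on_s = 300,
                      bleach_amp = 0, noise_sd = 0.01,
                      transient_rate_per_min = c(WAKE = 0, NREM = 0, REM = 0),
                      motion_rate_per_min = 0)
  hyp <- generate_hypnogram(cfg, 300)
  ph <- generate_photometry(cfg, hyp)
  f <- fit_bleach(lowpass_filter(ph$session$sig465, 120, 0.1),
                  ph$session$time_s)
  expect_lt(abs(f$amplitude), 0.05)
})

test_that("EEG band content and EMG tone track the hypnogram state", {
  mk <- function(state) {
    cfg <- synth_config(seed = 21, n_trials = 1, trial_on_s = 300,
                        state_mean_dwell_s = stats::setNames(
                          ifelse(c("WAKE", "NREM", "REM") == state, 1e7, 60),
                          c("WAKE", "NREM", "REM")))
    hyp <- generate_hypnogram(cfg, 300, init_state = state)
    generate_eeg_emg(cfg, hyp)
  }
  nrem <- mk("NREM"); rem <- mk("REM"); wake <- mk("WAKE")
  psd_n <- welch_psd(nrem$eeg, 400, nfft = 1024)
  expect_gt(bandpower(psd_n, 0.5, 4), bandpower(psd_n, 5, 9))
  psd_r <- welch_psd(rem$eeg, 400, nfft = 1024)
  expect_gt(bandpower(psd_r, 5, 9), bandpower(psd_r, 0.5, 4))
  expect_gt(sqrt(mean(wake$emg^2)), sqrt(mean(rem$emg^2)))
})

test_that("EEG TTL train is the photometry train shifted by the clock offset", {
  cfg <- synth_config(seed = 13, n_trials = 1, trial_on_s = 600,
                      clock_offset_s = 7, clock_drift_ppm = 0)
  hyp <- generate_hypnogram(cfg, 620)
  ph <- generate_photometry(cfg, hyp)
  eeg <- generate_eeg_emg(cfg, hyp)
  op <- detect_ttl_onsets(ph$session$ttl, 120)
  oe <- detect_ttl_onsets(eeg$ttl, 400)
  expect_length(oe, length(op))
  expect_true(all(abs(oe - (op + 7)) <= 1 / 400 + 1e-9))
})

test_that("LIF membrane stays subthreshold with no drive and obeys f-I ordering", {
  cfg <- synth_config(seed = 2)
  prot <- current_step_protocol(baseline_s = 1)
  rec0 <- generate_patch_recording(cfg, prot, spont_drive_pa = 0,
                                   fs_hz = 20000)
  expect_length(rec0$truth$spike_times_s[rec0$truth$spike_times_s <
                                           prot$sweeps$step_start_s[5]],
                0)  # nothing before the 30 pA step can fire (rheobase 40 pA)
  counts <- vapply(rec0$truth$sweep_spike_times_s, length, 0L)
  expect_equal(counts[prot$sweeps$current_pA < lif_params()$rheobase_pa],
               rep(0L, sum(prot$sweeps$current_pA < lif_params()$rheobase_pa)),
               ignore_attr = TRUE)
  expect_gte(counts[prot$sweeps$current_pA == 100],
             counts[prot$sweeps$current_pA == 50])
  # spontaneous drive off -> measured spontaneous rate is 0
  prot30 <- current_step_protocol(currents_pa = numeric(0), baseline_s = 30)
  rec30 <- generate_patch_recording(cfg, prot30, fs_hz = 5000)
  expect_equal(spontaneous_rate(rec30$recording), 0)
})

test_that("behavioral generator produces night-dominant activity and flaggable contamination", {
  for (seed in 1:5) {
    beh <- generate_behavior(synth_config(seed = seed), days = 1,
                             day_rate = 1, night_rate = 3)
    tot <- locomotor_totals(beh$locomotor,
                            list(day = c(0, 12), night = c(12, 24)))
    expect_gt(tot$total[tot$window == "night"],
              tot$total[tot$window == "day"])
  }
  beh <- generate_behavior(synth_config(seed = 7), n_startle = 100,
                           contamination_frac = 0.2)
  res <- analyze_startle(beh$startle)
  expect_equal(sum(res$excluded), sum(beh$startle$contaminated))
  expect_gt(sum(res$excluded), 9)
  expect_lt(sum(res$excluded), 32)
})

test_that("zero-amplitude startle response gives Vavg at the noise floor", {
  beh <- generate_behavior(synth_config(seed = 8), n_startle = 30,
                           response_amp_mv = 0)
  res <- analyze_startle(beh$startle)
  # mean rectified Gaussian noise: sd * sqrt(2/pi); allow generous slack
  floor_mv <- 0.02 * sqrt(2 / pi)
  expect_lt(abs(mean(res$vavg_mv) - floor_mv) / floor_mv, 0.25)
})
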