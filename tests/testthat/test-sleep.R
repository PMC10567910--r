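test_that("bout identification honors the strict >30 s rule", {
  # exactly 30 s of WAKE is not a bout
  expect_equal(nrow(find_bouts(new_hypnogram(rep("WAKE", 3)))), 0)
  expect_equal(nrow(find_bouts(new_hypnogram(rep("WAKE", 3)),
                               inclusive = TRUE)), 1)

  hyp <- new_hypnogram(c(rep("WAKE", 4), rep("NREM", 5)))
  b <- find_bouts(hyp)
  expect_equal(b$state, c("WAKE", "NREM"))
  expect_equal(b$duration_s, c(40, 50))
  expect_equal(b$start_s, c(0, 40))
})

test_that("sleep mode merges NREM and REM runs", {
  hyp <- new_hypnogram(c(rep("NREM", 2), rep("REM", 2), rep("WAKE", 1)))
  b <- find_bouts(hyp, mode = "sleep")
  expect_equal(b$state, "SLEEP")
  expect_equal(b$duration_s, 40)
})

test_that("bouts match brute-force run enumeration on random hypnograms", {
  set.seed(5)
  for (rep in 1:50) {
    labels <- random_labels(sample(5:80, 1))
    hyp <- new_hypnogram(labels)
    got <- as.data.frame(find_bouts(hyp))
    want <- oracle_bouts(labels, 10)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("binned state percentages match direct counting", {
  hyp <- new_hypnogram(rep("WAKE", 360))
  p <- percent_state_binned(hyp, "WAKE", 3600)
  expect_equal(p$percent, 100)

  hyp2 <- new_hypnogram(rep(c("WAKE", "NREM"), 180))
  expect_equal(percent_state_binned(hyp2, "WAKE", 3600)$percent, 50)

  set.seed(6)
  labels <- random_labels(720)
  hyp3 <- new_hypnogram(labels)
  p3 <- percent_state_binned(hyp3, "REM", 600)
  for (b in seq_len(nrow(p3))) {
    lab <- labels[(60 * (b - 1) + 1):(60 * b)]
    scored <- sum(lab != "ARTIFACT")
    want <- if (scored) 100 * sum(lab == "REM") / scored else NA_real_
    expect_equal(p3$percent[b], want)
  }
  # summed across states, scored bins total 100%
  tot <- sapply(c("WAKE", "NREM", "REM"), function(s)
    percent_state_binned(hyp3, s, 600)$percent)
  ok <- !is.na(rowSums(tot))
  expect_true(all(abs(rowSums(tot)[ok] - 100) < 1e-9))
})

test_that("latency to arousal follows the epoch arithmetic and precondition", {
  hyp <- new_hypnogram(c("NREM", "WAKE", "NREM", "NREM", "NREM", "WAKE"))
  expect_equal(latency_to_arousal(hyp, 0), 10)
  expect_equal(latency_to_arousal(hyp, 25), 25)  # mid-epoch, WAKE 3 epochs on
  expect_error(latency_to_arousal(hyp, 12), "not NREM")
  hyp2 <- new_hypnogram(rep("NREM", 5))
  expect_true(is.na(latency_to_arousal(hyp2, 0)))
})

test_that("Welch PSD localizes tones and preserves total power", {
  fs <- 400
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  psd <- welch_psd(sin(2 * pi * 4 * t), fs, nfft = 1024)
  f_peak <- psd$freq_hz[which.max(psd$power)]
  expect_lt(abs(f_peak - 4), fs / 1024 / 2 + 1e-9)

  set.seed(8)
  x <- rnorm(length(t), 0, 2)
  psd_n <- welch_psd(x, fs, nfft = 512)
  expect_lt(abs(bandpower(psd_n, 0, fs / 2) - var(x)) / var(x), 0.05)

  expect_true(all(welch_psd(rep(0, 2048), fs, nfft = 512)$power == 0))
  expect_error(welch_psd(rnorm(4096), fs, nfft = 777), "nfft")
})

test_that("spectrogram tracks a frequency switch and has the contracted bin count", {
  fs <- 400
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  x <- ifelse(t < 300, sin(2 * pi * 2 * t), sin(2 * pi * 8 * t))
  sg <- spectrogram_stft(x, fs, window_s = 30, overlap = 0.6)
  P <- attr(sg, "power")
  freqs <- attr(sg, "freqs_hz")
  times <- attr(sg, "times_s")
  expect_equal(ncol(P), floor((length(x) - 30 * fs) / (0.4 * 30 * fs)) + 1)
  dominant <- freqs[apply(P, 2, which.max)]
  expect_true(all(abs(dominant[times < 280] - 2) < 0.5))
  expect_true(all(abs(dominant[times > 320] - 8) < 0.5))

  # stationary tone: every column peaks at the tone bin
  sg2 <- spectrogram_stft(sin(2 * pi * 4 * t[1:(120 * fs)]), fs)
  dom2 <- attr(sg2, "freqs_hz")[apply(attr(sg2, "power"), 2, which.max)]
  expect_true(all(abs(dom2 - 4) < 0.2))
  expect_error(spectrogram_stft(x, fs, overlap = 0.99), "overlap")
})

test_that("bandpower integrates flat and empty spectra exactly", {
  psd <- structure(tibble::tibble(freq_hz = seq(0, 200, by = 0.5),
                                  power = 3), class = c("psd", "tbl_df",
                                                        "tbl", "data.frame"))
  expect_equal(bandpower(psd, 2, 10), 3 * 8)
  psd0 <- dplyr::mutate(psd, power = 0)
  expect_equal(bandpower(psd0, 0, 100), 0)
  expect_error(bandpower(psd, 10, 2), "band edges")
})

test_that("relative EMG amplitude normalizes to the pre-window NREM baseline", {
  fs <- 400
  ep <- 10
  hyp <- new_hypnogram(rep(c("NREM", "WAKE"), times = c(30, 30)))
  set.seed(9)
  n <- 600 * fs
  env <- rep(c(1, 2), each = n / 2)
  emg <- env * rnorm(n)
  w <- list(pre = c(0, 300), stim = c(300, 600))
  r <- relative_emg_amplitude(emg, fs, hyp, w)
  expect_equal(r$value[r$window == "pre"], 1.0, tolerance = 1e-12)
  expect_equal(r$value[r$window == "stim"], 2.0, tolerance = 0.05)

  hyp_w <- new_hypnogram(rep("WAKE", 60))
  expect_warning(r2 <- relative_emg_amplitude(emg, fs, hyp_w, w), "no NREM")
  expect_true(all(is.na(r2$value)))
})
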