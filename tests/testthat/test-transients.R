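make_ztrace <- function(z, fs = 120) {
  out <- tibble::tibble(time_s = (seq_along(z) - 1) / fs, trial = 1L,
                        z = z, z_unsmoothed = z)
  attr(out, "fs") <- fs
  attr(out, "trial_windows") <- tibble::tibble(trial = 1L, start_s = 0,
                                               end_s = length(z) / fs)
  class(out) <- c("zscore_trace", class(out))
  out
}

gauss_bump <- function(fs, amp = 1, fwhm_s = 0.5, len_s = 10, center_s = 5) {
  t <- seq(0, len_s - 1 / fs, by = 1 / fs)
  sigma <- fwhm_s / (2 * sqrt(2 * log(2)))
  amp * exp(-(t - center_s)^2 / (2 * sigma^2))
}

test_that("an isolated bump is one transient whose prominence is its height", {
  z <- make_ztrace(gauss_bump(120, amp = 1.0))
  ts <- detect_transients(z)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$prominence, 1.0, tolerance = 1e-6)
  expect_equal(ts$peak_time_s, 5, tolerance = 1 / 120)
  expect_equal(ts$width_s, 0.5, tolerance = 0.01)
})

test_that("bumps below the prominence gate are rejected", {
  z <- make_ztrace(gauss_bump(120, amp = 0.05))
  expect_equal(nrow(detect_transients(z)), 0)
})

test_that("the detector matches the exhaustive prominence/width oracle", {
  set.seed(123)
  for (rep in 1:30) {
    n <- 2000
    x <- if (rep %% 3 == 0) round(cumsum(rnorm(n)), 1) else cumsum(rnorm(n))
    got <- find_peaks(x)
    want <- oracle_peaks(x)
    expect_identical(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    expect_equal(got$width_s, want$width_s, tolerance = 1e-9)
  }
})

test_that("raising either threshold never adds a transient", {
  set.seed(7)
  z <- make_ztrace(cumsum(rnorm(5000)) / 10)
  base <- detect_transients(z, min_width_s = 0.05, min_prominence = 0.1)
  for (p in c(0.2, 0.5, 1)) {
    sub <- detect_transients(z, min_width_s = 0.05, min_prominence = p)
    expect_lte(nrow(sub), nrow(base))
    expect_true(all(sub$peak_time_s %in% base$peak_time_s))
  }
  for (w in c(0.1, 0.3)) {
    sub <- detect_transients(z, min_width_s = w, min_prominence = 0.1)
    expect_true(all(sub$peak_time_s %in% base$peak_time_s))
  }
})

test_that("per-state rates follow the counting arithmetic", {
  # 10 transients inside WAKE epochs totalling 5 minutes
  hyp <- new_hypnogram(rep(c("WAKE", "NREM"), times = c(30, 30)))
  ts <- new_transient_set(peak_time_s = seq(10, 290, length.out = 10),
                          prominence = rep(1, 10),
                          trial_windows = tibble::tibble(trial = 1L,
                                                         start_s = 0,
                                                         end_s = 600))
  r <- transient_rate_by_state(ts, hyp)
  expect_equal(r$rate_per_min[r$state == "WAKE"], 2.0)
  expect_equal(r$n[r$state == "NREM"], 0L)

  # all-ARTIFACT hypnogram -> undefined everywhere
  hyp_a <- new_hypnogram(rep("ARTIFACT", 60))
  r2 <- transient_rate_by_state(ts, hyp_a)
  expect_true(all(is.na(r2$rate_per_min)))
})

test_that("per-state counts sum to the total in scored time", {
  set.seed(31)
  cfg <- synth_config(seed = 31, n_trials = 1, trial_on_s = 600,
                      artifact_fraction = 0.1)
  hyp <- generate_hypnogram(cfg, 600)
  ph <- generate_photometry(cfg, hyp)
  z <- preprocess_photometry(ph$session)
  ts <- detect_transients(z, min_prominence = 2)
  r <- transient_rate_by_state(ts, hyp)
  st <- ifelse(is.na(match(floor(ts$peak_time_s / 10) + 1, hyp$epoch)),
               NA, hyp$state[floor(ts$peak_time_s / 10) + 1])
  expect_equal(sum(r$n), sum(st %in% c("WAKE", "NREM", "REM")))
})

test_that("prominence-by-state averages and flags empty states", {
  hyp <- new_hypnogram(rep("REM", 30))
  ts <- new_transient_set(peak_time_s = c(50, 150), prominence = c(0.2, 0.4),
                          trial_windows = tibble::tibble(trial = 1L,
                                                         start_s = 0,
                                                         end_s = 300))
  p <- transient_prominence_by_state(ts, hyp)
  expect_equal(p$mean_prominence[p$state == "REM"], 0.3)
  expect_true(is.na(p$mean_prominence[p$state == "WAKE"]))
})

test_that("state z-score means obey constant and trial-averaging arithmetic", {
  hyp <- new_hypnogram(rep(c("WAKE", "NREM", "REM"), each = 10))
  z <- make_ztrace(rep(0.7, 300 * 10), fs = 10)
  m <- zscore_by_state(z, hyp)
  expect_equal(m$mean_z, rep(0.7, 3), ignore_attr = TRUE)

  hyp_alt <- new_hypnogram(rep(c("WAKE", "NREM", "REM"), 10))
  z2 <- make_ztrace(c(rep(0.1, 1500), rep(0.3, 1500)), fs = 10)
  z2$trial <- rep(1:2, each = 1500)
  by_tr <- zscore_by_state(z2, hyp_alt, by_trial = TRUE)
  avg <- tapply(by_tr$mean_z, by_tr$state, mean)
  expect_true(all(abs(avg - 0.2) < 1e-12))
})

test_that("generated per-state contrasts are recovered end to end", {
  cfg <- synth_config(seed = 17, n_trials = 1, trial_on_s = 900,
                      transient_rate_per_min = c(WAKE = 10, NREM = 0, REM = 10))
  hyp <- generate_hypnogram(cfg, 900)
  ph <- generate_photometry(cfg, hyp)
  z <- preprocess_photometry(ph$session)
  m <- zscore_by_state(z, hyp)
  mz <- setNames(m$mean_z, m$state)
  expect_gt(mz["WAKE"], mz["NREM"])
  expect_gt(mz["REM"], mz["NREM"])
})
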