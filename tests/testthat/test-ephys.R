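test_that("spike detection handles flat traces and refractory doublets", {
  expect_length(detect_spikes(rep(-60, 5000), 20000), 0)
  # two crossings 1 ms apart -> one spike under the 2 ms refractory rule
  fs <- 20000
  vm <- rep(-60, 1000)
  vm[101:103] <- 10
  vm[121:123] <- 10  # 20 samples = 1 ms later
  expect_length(detect_spikes(vm, fs), 1)
  expect_length(detect_spikes(vm, fs, refractory_s = 0.0005), 2)
  expect_error(detect_spikes(c(1, NA), 20000), "non-finite")
})

test_that("detector recovers LIF ground-truth spikes to 1 ms", {
  cfg <- synth_config(seed = 33)
  prot <- current_step_protocol(baseline_s = 5)
  rec <- generate_patch_recording(cfg, prot, spont_drive_pa = 42,
                                  noise_mv = 0.5, fs_hz = 20000)
  got <- detect_spikes(rec$recording$vm_mv, 20000)
  want <- rec$truth$spike_times_s
  expect_length(got, length(want))
  expect_lt(max(abs(got - want)), 0.001)
})

test_that("spike detector equals the brute-force crossing scan", {
  set.seed(44)
  for (rep in 1:10) {
    vm <- -55 + 5 * cumsum(rnorm(50000)) / 50
    got <- detect_spikes(vm, 20000, threshold_mv = -40)
    want <- oracle_spikes(vm, 20000, threshold_mv = -40)
    expect_equal(got, want)
  }
})

test_that("spontaneous rate arithmetic and the 30 s baseline rule hold", {
  fs <- 20000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  vm <- rep(-60, length(t))
  # 15 spikes in the first 30 s
  for (k in 1:15) vm[abs(t - 2 * k + 1) < 0.0005] <- 10
  rec <- tibble::tibble(time_s = t, vm_mv = vm, i_pa = 0)
  attr(rec, "fs") <- fs
  attr(rec, "baseline_duration_s") <- 30
  class(rec) <- c("patch_recording", class(rec))
  expect_equal(spontaneous_rate(rec), 0.5)

  attr(rec, "baseline_duration_s") <- 29
  expect_error(spontaneous_rate(rec), "baseline")
})

test_that("f-I curves follow count arithmetic and LIF monotonicity", {
  fs <- 20000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  vm <- rep(-60, length(t))
  vm[abs(t - 2.05) < 0.0004] <- 10  # one spike inside the second step
  rec <- tibble::tibble(time_s = t, vm_mv = vm, i_pa = 0)
  attr(rec, "fs") <- fs
  attr(rec, "baseline_duration_s") <- 0
  attr(rec, "sweeps") <- tibble::tibble(current_pA = c(0, 10),
                                        step_start_s = c(0.5, 2),
                                        step_duration_s = 0.1)
  class(rec) <- c("patch_recording", class(rec))
  fi <- f_i_curve(rec)
  expect_equal(fi$rate_hz, c(0, 10))

  # noise-free LIF: zero below rheobase, non-decreasing above
  cfg <- synth_config(seed = 12)
  recL <- generate_patch_recording(cfg, current_step_protocol(baseline_s = 1),
                                   fs_hz = 20000)
  fiL <- f_i_curve(recL$recording)
  expect_true(all(fiL$rate_hz[fiL$current_pA < lif_params()$rheobase_pa] == 0))
  expect_true(all(diff(fiL$rate_hz) >= 0))
  # evoked rate at the top step matches the LIF closed form within one spike
  lif <- lif_params()
  v_inf <- lif$e_l_mv + lif$r_gohm * 100
  isi <- lif$refractory_s +
    lif$tau_s * log((v_inf - lif$v_reset_mv) / (v_inf - lif$v_th_mv))
  t_first <- lif$tau_s * log((v_inf - lif$e_l_mv) / (v_inf - lif$v_th_mv))
  expected <- floor((0.1 - t_first) / isi) + 1
  expect_lt(abs(fiL$n_spikes[fiL$current_pA == 100] - expected), 2)
})

test_that("overlapping step protocols are rejected", {
  rec <- tibble::tibble(time_s = seq(0, 1, by = 5e-5), vm_mv = -60, i_pa = 0)
  attr(rec, "fs") <- 20000
  attr(rec, "sweeps") <- tibble::tibble(current_pA = c(0, 10),
                                        step_start_s = c(0.1, 0.15),
                                        step_duration_s = 0.1)
  class(rec) <- c("patch_recording", class(rec))
  expect_error(f_i_curve(rec), "overlapping")
})

test_that("restriction to spontaneously firing cells reports the retained fraction", {
  cfg <- synth_config(seed = 3)
  prot <- current_step_protocol(currents_pa = numeric(0), baseline_s = 30)
  cells <- c(
    lapply(1:3, function(i) generate_patch_recording(
      synth_config(seed = i), prot, spont_drive_pa = 50, fs_hz = 5000)),
    lapply(4:10, function(i) generate_patch_recording(
      synth_config(seed = i), prot, spont_drive_pa = 0, fs_hz = 5000))
  )
  r <- restrict_to_spontaneous(cells)
  expect_equal(r$fraction, 0.3)
  expect_length(r$cells, 3)
  expect_true(all(r$rates_hz[1:3] > 0))

  all_silent <- restrict_to_spontaneous(cells[4:10])
  expect_length(all_silent$cells, 0)
})
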