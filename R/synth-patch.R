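#' Current-step stimulation protocol
#'
#' The standard current-clamp protocol: a spontaneous-firing baseline of at
#' least 30 s, then 100 ms current steps from -10 to 100 pA delivered every
#' 2 s.
#'
#' @param currents_pa Step currents (pA), one sweep per entry.
#' @param step_duration_s Step length (s, default 0.1).
#' @param period_s Time between step onsets (s, default 2).
#' @param baseline_s Baseline length before the first step (s, default 30).
#' @return A `current_protocol` list with a `sweeps` tibble
#'   (`current_pA`, `step_start_s`, `step_duration_s`).
#' @export
current_step_protocol <- function(currents_pa = seq(-10, 100, by = 10),
                                  step_duration_s = 0.1,
                                  period_s = 2,
                                  baseline_s = 30) {
  stopifnot(step_duration_s > 0, period_s >= step_duration_s, baseline_s >= 0)
  sweeps <- tibble::tibble(
    current_pA = currents_pa,
    step_start_s = baseline_s + (seq_along(currents_pa) - 1) * period_s,
    step_duration_s = step_duration_s
  )
  structure(list(sweeps = sweeps, baseline_s = baseline_s,
                 period_s = period_s,
                 total_s = baseline_s + length(currents_pa) * period_s),
            class = "current_protocol")
}

#' Leaky integrate-and-fire membrane parameters
#'
#' @param e_l_mv Resting (leak) potential, mV.
#' @param r_gohm Input resistance, gigaohm (mV per pA).
#' @param tau_s Membrane time constant, s.
#' @param v_th_mv Spike threshold, mV.
#' @param v_reset_mv Post-spike reset, mV.
#' @param refractory_s Absolute refractory period, s.
#' @param v_peak_mv Rendered spike peak, mV (above 0 so threshold-crossing
#'   detectors see it).
#' @return A `lif_params` list. The implied rheobase is
#'   `(v_th_mv - e_l_mv) / r_gohm` (40 pA with the defaults).
#' @export
lif_params <- function(e_l_mv = -60, r_gohm = 0.5, tau_s = 0.02,
                       v_th_mv = -40, v_reset_mv = -55,
                       refractory_s = 0.002, v_peak_mv = 30) {
  stopifnot(v_th_mv > e_l_mv, v_reset_mv < v_th_mv, tau_s > 0, r_gohm > 0)
  structure(list(e_l_mv = e_l_mv, r_gohm = r_gohm, tau_s = tau_s,
                 v_th_mv = v_th_mv, v_reset_mv = v_reset_mv,
                 refractory_s = refractory_s, v_peak_mv = v_peak_mv,
                 rheobase_pa = (v_th_mv - e_l_mv) / r_gohm),
            class = "lif_params")
}

#' Simulate a whole-cell current-clamp recording
#'
#' Integrates a leaky integrate-and-fire membrane through the current-step
#' protocol, with an optional constant spontaneous drive and optional
#' membrane noise. Spikes are rendered as brief stereotyped waveforms
#' (1 ms up/downstroke to `v_peak_mv`) so that threshold-crossing spike
#' detection applies; the true spike (threshold-crossing) times are
#' returned as ground truth. The noise-free path is integrated with the
#' exact piecewise closed form of the LIF equation; with noise an
#' Euler-Maruyama loop is used.
#'
#' @param cfg A [synth_config()] (supplies the seed).
#' @param protocol A [current_step_protocol()].
#' @param spont_drive_pa Constant bias current (pA); above the rheobase it
#'   produces regular spontaneous firing.
#' @param noise_mv Membrane noise scale (mV); 0 gives the deterministic LIF.
#' @param fs_hz Sampling rate (Hz, default 20000).
#' @param lif A [lif_params()].
#' @return List with `recording` (tibble `time_s`, `vm_mv`, `i_pa`;
#'   attributes `fs`, `sweeps`, `baseline_duration_s`; class
#'   `patch_recording`) and `truth` (spike times overall, in baseline, and
#'   per sweep step window).
#' @examples
#' cfg <- synth_config(seed = 5)
#' prot <- current_step_protocol(currents_pa = c(0, 50), baseline_s = 1)
#' rec <- generate_patch_recording(cfg, prot, fs_hz = 5000)
#' length(rec$truth$spike_times_s)
#' @export
generate_patch_recording <- function(cfg, protocol = current_step_protocol(),
                                     spont_drive_pa = 0, noise_mv = 0,
                                     fs_hz = 20000, lif = lif_params()) {
  stopifnot(inherits(cfg, "synth_config"), inherits(protocol, "current_protocol"))
  stopifnot(all(protocol$sweeps$step_duration_s > 0))
  n <- as.integer(round(protocol$total_s * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz

  # injected current per sample: bias plus the step train
  i_pa <- rep(spont_drive_pa, n)
  for (k in seq_len(nrow(protocol$sweeps))) {
    i0 <- as.integer(round(protocol$sweeps$step_start_s[k] * fs_hz)) + 1L
    i1 <- as.integer(round((protocol$sweeps$step_start_s[k] +
                              protocol$sweeps$step_duration_s[k]) * fs_hz))
    i_pa[i0:min(i1, n)] <- i_pa[i0:min(i1, n)] + protocol$sweeps$current_pA[k]
  }

  withr_seed(cfg$seed, "patch", {
    if (noise_mv == 0) {
      sim <- lif_exact(t, i_pa, fs_hz, lif)
    } else {
      sim <- lif_euler(t, i_pa, fs_hz, lif, noise_mv)
    }
    vm <- render_spikes(sim$vm, sim$spike_times, fs_hz, lif)

    recording <- tibble::tibble(time_s = t, vm_mv = vm, i_pa = i_pa)
    attr(recording, "fs") <- fs_hz
    attr(recording, "sweeps") <- protocol$sweeps
    attr(recording, "baseline_duration_s") <- protocol$baseline_s
    class(recording) <- c("patch_recording", class(recording))

    sw <- protocol$sweeps
    by_sweep <- lapply(seq_len(nrow(sw)), function(k) {
      sim$spike_times[sim$spike_times >= sw$step_start_s[k] &
                        sim$spike_times < sw$step_start_s[k] + sw$step_duration_s[k]]
    })
    truth <- list(spike_times_s = sim$spike_times,
                  baseline_spike_times_s =
                    sim$spike_times[sim$spike_times < protocol$baseline_s],
                  sweep_spike_times_s = by_sweep)
    list(recording = recording, truth = truth)
  })
}

# exact piecewise integration of the deterministic LIF over the
# piecewise-constant current trace; each sample is written exactly once
lif_exact <- function(t, i_pa, fs, lif) {
  n <- length(t)
  vm <- numeric(n)
  spikes <- numeric(0)
  seg_start <- c(1L, which(diff(i_pa) != 0) + 1L)
  seg_end <- c(seg_start[-1] - 1L, n)
  v0 <- lif$e_l_mv
  t0 <- t[1]
  ptr <- 1L  # next sample index to fill
  fill_decay <- function(upto_t) {
    # fill samples in [t0, upto_t) with the decay from (t0, v0)
    last <- min(n, as.integer(ceiling(upto_t * fs - 1e-9)))
    if (ptr <= last) {
      sel <- ptr:last
      vm[sel] <<- v_inf + (v0 - v_inf) * exp(-(t[sel] - t0) / lif$tau_s)
      ptr <<- last + 1L
    }
  }
  for (s in seq_along(seg_start)) {
    b <- seg_end[s]
    v_inf <- lif$e_l_mv + lif$r_gohm * i_pa[seg_start[s]]
    t_end <- t[b] + 1 / fs
    while (t0 < t_end) {
      can_spike <- v_inf > lif$v_th_mv && v0 < v_inf
      t_star <- if (can_spike)
        t0 + lif$tau_s * log((v_inf - v0) / (v_inf - lif$v_th_mv)) else Inf
      if (t_star >= t_end) {
        fill_decay(t_end)
        v0 <- v_inf + (v0 - v_inf) * exp(-(t_end - t0) / lif$tau_s)
        t0 <- t_end
      } else {
        fill_decay(t_star)
        spikes <- c(spikes, t_star)
        t_ref_end <- t_star + lif$refractory_s
        last <- min(n, as.integer(ceiling(t_ref_end * fs - 1e-9)))
        if (ptr <= last) {
          vm[ptr:last] <- lif$v_reset_mv
          ptr <- last + 1L
        }
        v0 <- lif$v_reset_mv
        t0 <- t_ref_end
      }
    }
  }
  if (ptr <= n) vm[ptr:n] <- v0
  list(vm = vm, spike_times = spikes)
}

# Euler-Maruyama integration with additive membrane noise
lif_euler <- function(t, i_pa, fs, lif, noise_mv) {
  n <- length(t)
  dt <- 1 / fs
  vm <- numeric(n)
  spikes <- numeric(0)
  v <- lif$e_l_mv
  ref_until <- -Inf
  noise <- noise_mv * sqrt(dt / lif$tau_s) * stats::rnorm(n)
  for (i in seq_len(n)) {
    if (t[i] < ref_until) {
      v <- lif$v_reset_mv
    } else {
      v_inf <- lif$e_l_mv + lif$r_gohm * i_pa[i]
      v <- v + dt / lif$tau_s * (v_inf - v) + noise[i]
      if (v >= lif$v_th_mv) {
        spikes <- c(spikes, t[i])
        v <- lif$v_reset_mv
        ref_until <- t[i] + lif$refractory_s
      }
    }
    vm[i] <- v
  }
  list(vm = vm, spike_times = spikes)
}

# overwrite the membrane trace with a stereotyped spike waveform: 0.5 ms
# upstroke to v_peak, 0.5 ms downstroke to reset
render_spikes <- function(vm, spike_times, fs, lif) {
  if (!length(spike_times)) return(vm)
  half <- max(1L, as.integer(round(0.0005 * fs)))
  up <- seq(lif$v_th_mv, lif$v_peak_mv, length.out = half + 1)[-1]
  down <- seq(lif$v_peak_mv, lif$v_reset_mv, length.out = half + 1)[-1]
  wf <- c(up, down)
  n <- length(vm)
  for (ts in spike_times) {
    i0 <- as.integer(round(ts * fs)) + 1L
    idx <- i0:min(i0 + length(wf) - 1L, n)
    if (i0 <= n) vm[idx] <- wf[seq_along(idx)]
  }
  vm
}

#' Simulate a population of patch-clamped cells
#'
#' Draws one spontaneous bias current per cell from a normal distribution
#' positioned so that a fraction `spont_frac` of cells sits above the LIF
#' rheobase (and therefore fires spontaneously), then simulates each cell
#' through the protocol.
#'
#' @inheritParams generate_patch_recording
#' @param n_cells Number of cells.
#' @param spont_frac Target fraction of spontaneously firing cells
#'   (default 0.3).
#' @param drive_sd_pa Between-cell sd of the bias current (pA).
#' @return List of per-cell results as from [generate_patch_recording()],
#'   with the drawn drives in `attr(, "drives_pa")`.
#' @export
generate_patch_population <- function(cfg, n_cells,
                                      protocol = current_step_protocol(),
                                      spont_frac = 0.3, drive_sd_pa = 8,
                                      noise_mv = 0, fs_hz = 20000,
                                      lif = lif_params()) {
  mu <- lif$rheobase_pa - stats::qnorm(1 - spont_frac) * drive_sd_pa
  drives <- withr_seed(cfg$seed, "patchpop",
                       stats::rnorm(n_cells, mu, drive_sd_pa))
  cells <- lapply(seq_len(n_cells), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * i
    generate_patch_recording(cfg_i, protocol, spont_drive_pa = drives[i],
                             noise_mv = noise_mv, fs_hz = fs_hz, lif = lif)
  })
  attr(cells, "drives_pa") <- drives
  cells
}
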