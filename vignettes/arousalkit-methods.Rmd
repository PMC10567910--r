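---
title: "Methods: multimodal sleep-wake arousal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal sleep-wake arousal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalkit)
```

`arousalkit` analyses simultaneous fiber-photometry and EEG/EMG recordings
of rodent sleep-wake behaviour, plus the patch-clamp and behavioural
readouts that typically accompany such studies. This vignette explains the
models and procedures the package implements, the parameters that matter,
and the design decisions taken where several reasonable choices existed.

## The measurement model

A fiber-photometry rig reports two demodulated fluorescence channels: a
Ca²⁺-dependent signal (465 nm excitation) and a Ca²⁺-independent isosbestic
reference (405 nm). Both share three nuisance components — a slow
photobleaching decay, abrupt motion artifacts from fiber displacement, and
broadband sensor noise — while only the signal channel carries the Ca²⁺
transients of interest:

$$ S(t) = B(t) + \sum_i A\,k(t - t_i) + M(t) + \varepsilon_S(t), \qquad
   R(t) = B(t) + M(t) + \varepsilon_R(t), $$

with bleaching $B(t) = a\,e^{-t/\tau} + c$ and a transient kernel
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$. The recording runs in 15-min
trials separated by 15-min breaks (six trials by default), and a 1 s TTL
pulse every 3 min is recorded by both the photometry console and the
EEG/EMG system, tying their clocks together. EEG/EMG is sampled at 400 Hz
and scored in 10 s epochs as WAKE, NREM, REM or ARTIFACT.

## Preprocessing chain (`preprocess_photometry()`)

Per trial window:

1. each channel is zero-phase low-pass filtered at 0.1 Hz and an
   exponential $a\,e^{-t/\tau} + c$ is fitted to the result
   (`fit_bleach()`, Levenberg–Marquardt with log-linear initialization);
2. the fitted curve is subtracted from the **raw** channel;
3. the bleach-corrected reference is subtracted from the bleach-corrected
   signal, cancelling shared motion;
4. the result is robustly standardized: subtract the median, divide by the
   median absolute deviation (MAD);
5. the z-trace is zero-phase low-pass filtered at 5 Hz.

Choices worth stating explicitly:

* **MAD without the 1.4826 consistency constant.** The plain MAD is used
  as the scale; `mad_constant` restores the normal-consistent variant if
  wanted. Consequently "z units" here are MAD units, not standard
  deviations.
* **Raw-trace subtraction.** The fitted bleach curve is subtracted from
  the raw channel, not from its low-passed version; the low-passed copy
  exists only to stabilize the fit.
* **Per-trial scope.** Median/MAD are computed per 15-min trial (the unit
  of recording); `z_scope = "session"` pools trials instead.
* **Unscaled reference subtraction.** Motion correction is a 1:1
  subtraction, which cancels artifacts exactly when they enter both
  channels with equal amplitude (how the generator builds them). A
  regression-scaled variant (`scaled_reference = TRUE`) exists for data
  where the channels' artifact gains differ.
* **Filters.** All filters are 4th-order Butterworth applied
  forward-backward (zero phase), cutoff = −3 dB point, with reflection
  padding. For normalized cutoffs below 1/250 (the 0.1 Hz bleach filter at
  120 Hz sampling) the filter runs on a decimated copy and is interpolated
  back; direct recursion at such extreme cutoffs is numerically unstable.
* **Degenerate scale guard.** If the motion-corrected trace has exactly
  zero MAD (e.g. identical channels in a noise-free null construction) the
  division is skipped, leaving a median-centred trace. Otherwise a null
  input would be amplified to MAD 1 by construction.
* **Bleach fit fallback.** Flat or rising traces (no decay to fit) return
  amplitude 0 and offset = mean; `tau_s` is then reported as the record
  span, an arbitrary positive placeholder.

## Transient detection (`detect_transients()`)

Local maxima are screened by **topographic prominence** — the peak height
above the higher of the two lowest saddle levels separating it from the
nearest higher samples on each side (or the trace ends) — and by width at
half prominence (linear interpolation). Plateau maxima take their leftmost
sample. The reference implementation is a compiled walk identical in
semantics to the classic `findpeaks` routine; the test suite pins it
against an exhaustive $O(n^2)$ oracle on hundreds of random traces.

Defaults are minimum width 80 ms and minimum prominence 0.1 z — the
conventional screening values for smooth in-vivo recordings. **These are
not the right operating point for this package's synthetic data**: the
median/MAD z-score fixes the broadband noise floor near 1 MAD unit, and
after the 5 Hz low-pass the noise sd is still ≈ 0.43 z, so noise peaks
reach prominences around 2. Recovery analyses on generated data therefore
use `min_prominence = 2.5`, calibrated once against the synthetic noise
floor: it sits above the noise-peak prominence tail (~2.3) and well below
the generated transient prominence (5 × noise sd ≈ 7.4 z after MAD
scaling). At that operating point the detector scores ≥ 96% sensitivity
with ≤ 1% false discoveries across seeds.

Two resolution facts shape the rate statistics:

* **Event matching window.** When detections are scored against ground
  truth, a true event counts as recalled if a detection lies within the
  transient kernel's full width at half maximum (1.62 s at the default
  rise 0.2 s / decay 1.5 s). Events closer together than the indicator
  kinetics are physically indistinguishable, so no narrower window is
  meaningful.
* **Dead-time correction.** Peak counting undercounts at high rates for
  the same reason: events closer than the kernel width merge into one
  peak. `transient_rate_by_state(deadtime_s = ...)` optionally inverts the
  paralyzable dead-time relation $r_{obs} = \lambda e^{-\lambda\tau}$
  (τ = kernel FWHM is the natural choice) to recover the underlying event
  rate; at 10 events/min the raw peak rate is ~20% low and the corrected
  estimate is unbiased. The default (`deadtime_s = 0`) reports the raw
  peak rate — the quantity conventionally plotted as "transient
  frequency".

Transients are assigned to vigilance states by the epoch containing the
**peak** time (mapped through the fitted clock relation), and rates divide
by the non-ARTIFACT time of each state inside the recorded trial windows.

## Clock alignment (`fit_clock_map()`)

TTL onsets are rising edges at half the channel maximum, gated at ≥ 0.5 s
width. The two onset trains are matched greedily (nearest neighbour after
a coarse offset from the first pulses) and an affine map
$t_{EEG} = \alpha + \beta\,t_{phot}$ is fitted by least squares. The
affine model strictly generalizes a pure offset; with only two pulses the
line is exact. Drift outside (0.9, 1.1) is rejected as implausible for
laboratory clocks. Sub-sample edge interpolation is deliberately not
attempted; with 30 pulses the quantization-limited fit recovers an
injected offset to ≲ 0.1 ms and drift to ≲ 0.1 ppm, far inside the 10 ms /
5 ppm the analysis needs.

## Sleep architecture and spectra

* **Bouts** are maximal runs of one non-ARTIFACT state lasting strictly
  more than 30 s — the literal "> 30 s" convention, so exactly 30 s is not
  a bout (`inclusive = TRUE` relaxes this). `mode = "sleep"` merges
  NREM+REM before run-length analysis.
* **Percent-state time** is computed per bin over non-ARTIFACT epochs
  only; all-ARTIFACT bins are undefined (NA), and scored WAKE/NREM/REM
  percentages sum to 100 per bin.
* **Latency to arousal** is the time from a stimulus onset (which must lie
  in a NREM epoch, else the trial is rejected) to the start of the first
  WAKE epoch at or after it.
* **Welch PSD** uses Hann windows of 512 or 1024 samples with 50% overlap
  and one-sided density scaling; the overlap and window family are
  standard defaults, stated here because only the segment sizes are
  conventionally fixed. The density scaling is verified by Parseval's
  relation (white-noise PSD integrates to the variance within 5%).
* **Spectrograms** are magnitude-squared STFTs, 30 s Hann window, 60%
  overlap, then smoothed along the *time* axis by a rolling Hann-weighted
  average of 5 bins (the smoothing axis and width are choices; frequency
  smoothing is left to the window itself).
* **Relative EMG amplitude** is the per-epoch RMS of the 10 Hz high-passed
  EMG, normalized to the mean over NREM epochs inside the pre-stimulation
  window, so the sleeping baseline maps to 1. RMS (not mean-rectified) is
  the chosen amplitude functional.

## Transitions (`find_transitions()`, `transition_triggered()`)

Four transition kinds are tracked: NREM→WAKE, WAKE→NREM, NREM→REM,
REM→WAKE. A boundary is retained when the flanking epochs are pure: 15 s
of consolidation per side on a 10 s grid is enforced as **2 full epochs
(20 s) per side** — conservative rounding; and purity is required on
*both* sides by default (`both_sides = FALSE` checks only the
pre-transition flank). Transition-triggered averaging resamples the
z-trace on a common grid around each boundary, drops events whose windows
leave the recorded trials (reporting the count), normalizes each row to
its own maximum (rows with non-positive maxima are flagged and left
unnormalized), and returns mean and SEM across the normalized rows.

## Patch-clamp analysis

Spikes are upward threshold crossings (−20 mV default, 2 ms refractory);
the detector is pinned against a brute-force scan. The spontaneous rate is
the baseline spike count over the baseline duration, and baselines under
30 s are rejected outright rather than extrapolated. The f-I curve counts
spikes strictly inside each 100 ms step of the −10…100 pA protocol.
Because spontaneous firing is a meaningful cell phenotype,
`restrict_to_spontaneous()` filters a population to cells with positive
baseline rate and reports the retained fraction.

## What the synthetic generator emulates — and what it does not

`synth_config()` fixes the study conditions: 10 s epochs, six 15-min
trials with 15-min breaks, 120 Hz photometry (post-demodulation), 400 Hz
EEG/EMG, TTL every 3 min. The hypnogram is a semi-Markov chain with
geometric dwell times on the epoch grid (memoryless per epoch — the
simplest law consistent with epoch-based scoring; mean dwells default to
120/120/60 s for WAKE/NREM/REM and REM exits only to WAKE). Photometry is
generated directly at 120 Hz rather than as a 12 kHz modulated carrier:
every analysis step operates on demodulated signals, and 120 Hz is more
than 20× the final 5 Hz cutoff. Transients are state-dependent Poisson
events with a difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s —
typical slow indicator kinetics); motion pulses are biphasic and enter
both channels with identical amplitude; noise is white and independent
between channels, with sd 0.05 a.u. against a default bleach of
5·exp(−t/300 s)+2. EEG is band-filtered noise mixed with state-dependent
weights (delta-dominant NREM, theta-dominant REM, broadband wake), EMG is
enveloped white noise (WAKE ≫ NREM > REM), and membrane traces come from a
leaky integrate-and-fire neuron (rest −60 mV, threshold −40 mV, 0.5 GΩ,
20 ms; rheobase 40 pA) with rendered spike waveforms.

Passing tests on these data demonstrate that the *algorithms* do what they
claim — parameters are recovered, oracles agree, orderings hold. They do
not certify performance on real recordings: real bleach is not perfectly
single-exponential, motion gains differ between wavelengths, EEG is not a
stationary band mixture, real spike shapes vary, and real photometry noise
is far smoother than the white noise used here (which is why the
transient-screening defaults and the synthetic operating point differ).

## Problem sizes and numerical notes

The shipped validation suite runs the full chain on 30-minute two-trial
sessions across 20 seeds for rate recovery, 200 random traces of 10⁴
samples for the detector oracle, 1000 random hypnograms for the transition
oracle, and 100 simulated cells for the spontaneous-fraction check —
problem sizes chosen to exercise every code path at desk scale while
keeping the whole suite in a few minutes. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at
slightly smaller sizes. Ties in peak plateaus break leftmost; band-power
integrals interpolate the band edges so a flat density integrates exactly;
empty states, all-ARTIFACT bins, single-event SEMs and sub-30 s baselines
are all defined (NA/flag/reject) rather than silent.

## Known limitations

No deconvolution or spike inference from the calcium trace; no automatic
sleep staging or artifact detection; no hemodynamic or wavelength-gain
correction beyond the 1:1 reference subtraction; EDF I/O is out of scope —
EEG/EMG travel as plain columnar CSV; group-level inferential statistics
are left to the standard R toolchain (`aov`, `kruskal.test`, …) on the
tidy outputs.
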