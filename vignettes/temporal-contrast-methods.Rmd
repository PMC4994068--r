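---
title: "Quantifying temporal contrast enhancement in olfactory responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal contrast enhancement in olfactory responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfcontrast)
```

## The problem this package addresses

When a fly exits an odor plume, the offset of the stimulus is as informative
as its onset. Intense odor pulses, however, leave the peripheral olfactory
sensory neurons (OSNs) firing for seconds after the odor is gone, and the
lingering odor itself decays slowly a few centimeters away from its source.
Presynaptic inhibition at the OSN axon terminals — fast ionotropic GABA-A
receptor conductances together with slow metabotropic GABA-B signalling —
truncates this sustained activity, producing temporally contrast-enhanced
voltage responses in the terminals and faster behavioral reactions to pulse
termination.

`olfcontrast` implements the full quantification chain for this phenomenon:

1. **Trace preprocessing** (`roi_average()`, `fit_bleach()`, `detrend()`,
   `boxcar()`, `dff()`, or `process_trace()` for the whole chain): ROI
   spatial averaging of small-chip imaging movies, double-exponential
   photobleaching correction, iterated box-car smoothing, percent dF/F.
2. **Contrast statistics** (`sharpness_max()`, `sharpness_offset()`,
   `sharpness_timecourse()`, `decay_time()`).
3. **Spike analysis** (`bandpass()`, `detect_spikes()`, `sort_units()`,
   `firing_rate()`, `postpulse_comparison()`) for extracellular sensillum
   recordings.
4. **Behavioral kinematics** (`kalman_track()`, `delta_d()`,
   `mean_distance_timecourse()`, `radial_velocity()`,
   `postpulse_kinetics()`, `net_displacement()`) for flies in a circular
   odor arena.
5. **A synthetic-data generator** (`make_odor_pulse()`, `osn_rate()`,
   `apply_presynaptic_inhibition()`, `sample_spikes()`, `render_*()`,
   `simulate_flies()`) that emulates all of the above recording modalities,
   so every stage of the chain is verifiable without raw recordings.

## The contrast statistics

The **sharpness coefficient** measures how completely neuronal activity has
returned toward baseline a fixed delay after odor offset:

$$\mathrm{sharpness} = \frac{\mathrm{ref} - x(t_\mathrm{off} + \Delta)}{\mathrm{ref}},
\qquad \Delta = 1.5\ \mathrm{s\ by\ default.}$$

Two reference conventions are implemented. `sharpness_max()` uses the
maximum of the trace over the stimulus window — 1 means the response has
fully returned to baseline (100% temporal contrast), 0 means the postpulse
value still equals the in-pulse peak. `sharpness_offset()` references the
value at the commanded odor-offset time instead, which discounts sensory
adaptation during the pulse; it is the variant used for time-resolved
analysis (`sharpness_timecourse()` evaluates it on a grid of delays).

Values are looked up at the nearest sample — the statistic reports what the
recording contains, not an interpolation. Negative coefficients (postpulse
rebound above the reference) are reported unclamped, and on traces that can
go below baseline (dF/F during hyperpolarization) the coefficient can
exceed 1; both carry real information about postpulse dynamics. On
nonnegative traces such as firing rates the coefficient never exceeds 1.

The **decay time** `decay_time()` is the time a trace takes to fall from its
peak to 36.8% (1/e) of the peak, with the crossing linearly interpolated
between samples so sub-sample time constants are recoverable. It is the
statistic used to show that odor pulses decay slowly more than 3–4 cm from
the port, and it returns `NA` (rather than erroring) when the trace never
reaches the threshold.

## Preprocessing choices

* **Bleach model**: `b(t) = a_f e^{-t/\tau_f} + a_s e^{-t/\tau_s} + c`,
  fitted by multi-start Levenberg–Marquardt least squares over a grid of
  time-constant decades (0.3–100 s by default). The two exponentials are
  nearly collinear on short recordings, so the fit is performed directly on
  the residual function and the best converged start is kept; components are
  returned with `tau_fast_s < tau_slow_s`.
* **Response exclusion**: by default the stimulus/response window should be
  excluded from the bleach fit so the response does not bias the baseline.
  When the odor drives a *sustained* component, the exclusion window must
  cover the sustained tail too (several of its decay constants past offset);
  the package's own verification uses onset − 0.2 s through offset + 10 s on
  20 s recordings, which recovers injected response peaks to well within 2%.
  Fitting through the response is available by passing `exclude_window =
  NULL`.
* **Correction mode**: `divide` (default) treats bleaching as
  multiplicative, yielding a flat unit baseline that feeds naturally into
  dF/F; `subtract` is retained for additive use cases.
* **Smoothing**: eight rounds of a centered box-car, default width 3
  samples (24 ms at the 125 Hz voltage-imaging frame rate), which preserves
  the ~100 ms response features. Edges are handled by reflection so
  repeated rounds do not droop at the endpoints; width 1 is the identity.
* **dF/F**: `100 (F - F_0)/F_0` with `F_0` the mean over a pre-stimulus
  baseline window. Voltage indicators of the ArcLight family dim on
  depolarization, so processed traces are conventionally inverted
  (`invert = TRUE` in `process_trace()`) to plot responses upward.

## Spike analysis choices

Extracellular traces are band-passed 300 Hz – 2 kHz (zero-phase Butterworth,
order 3 per pass, with mean removal and odd-reflection padding so DC is
rejected exactly and filter startup transients do not masquerade as events).
Detection thresholds at `k_mad = 5` times the median absolute deviation — a
robust noise estimate that tolerates spike contamination — times events at
the local absolute extremum within 1 ms of the crossing, and suppresses
events closer than 2 ms keeping the larger one. Two-unit sorting is 1-D
2-means on event amplitudes, initialized deterministically at the 25th/75th
percentiles; the larger-amplitude cluster is labeled "A" (the convention for
the larger spike of a two-neuron sensillum), and degenerate inputs fall back
to a single unit with a warning. Rates use a sliding 100 ms rectangular
window stepped at 8 ms (a Gaussian kernel is available). Overlapping-spike
resolution and waveform-shape sorting are out of scope.

## Behavioral kinematics choices

Tracking is a constant-velocity Kalman filter per fly with greedy
nearest-neighbor assignment within a gate (distance ties broken by the lower
track id) — deliberately the simple tracker architecture used for arena
assays — with Hungarian-style globally optimal assignment left out. Tracks
must accrue 3 consecutive detections before being reported and coast at most
2 frames before terminating.

Kinematics follow the arena conventions: positions in cm with the origin at
the arena center, ports on the boundary of the 5 cm-radius arena, 30 frames
per second. `delta_d()` computes `d_0 - d_t` so positive values mean
movement toward the port (attraction). The 10 s-pulse analysis samples
distance every 0.5 s for 35 s (70 bins); the 1 s-pulse analysis computes
signed *radial* velocity (displacement along the port axis per window, not
path speed — path speed is available as an option) in 1 s windows after
odor offset, stratified by initial distance at 3 cm.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes:

* **Odor pulses**: first-order rise/decay PID waveforms; a distance profile
  (`arena_decay_profile()`) makes the peak decay and the decay tau rise
  steeply beyond 3–4 cm from the port, emulating lingering odor.
* **OSN rates**: spontaneous rate, concentration gain with first-order
  adaptation, a threshold-gated sustained component (threshold placed
  between the weak 1:25 and strong 1:5 pulse amplitudes, since sustained
  firing appears only at high intensity), and poststimulus inhibition after
  weak pulses. The end-of-pulse adaptation obeys the closed-form
  exponential-relaxation solution, which the tests exploit.
* **Presynaptic inhibition**: two causal unit-area exponential kernels
  driven by the rate — fast (GABA-A-like, 0.1 s) and slow (GABA-B-like,
  1.5 s) — subtracted and clamped at zero. The model is deliberately
  phenomenological: it reproduces the qualitative pattern that the slow
  kernel truncates the sustained tail, the fast kernel shapes the early
  response, and only joint inhibition produces the full sharpening and the
  full amplitude suppression. Genotype emulation simply disables kernels.
* **Indicator fluorescence**: drive scaled by a soft-saturating map onto a
  double-exponential bleach baseline; negative scale for voltage indicators
  (dimming), positive with a rise/decay calcium kernel for GCaMP-like
  indicators, at 125 and 40 Hz frame rates respectively, optionally expanded
  into an 80 × 80 pixel movie with per-pixel noise.
* **Extracellular traces**: a fixed 2 ms biphasic template per spike at
  10 kHz, 2:1 unit-amplitude ratio by default, additive white noise; spike
  trains by Poisson thinning with absolute refractoriness.
* **Arena behavior**: random-walk flies with heading diffusion and a
  concentration-dependent signed radial drift, sensing latency, and a
  persistence window that lets directed movement outlast the local odor;
  reflective boundary.

What it does **not** emulate: biophysical conductance dynamics, receptor
kinetics, saturation of the PID itself, imaging motion artifacts,
multi-glomerular interactions, fly–fly interactions, or posture. Passing
tests therefore demonstrate that the *analysis chain* is correct and
well-calibrated on data with the assumed structure — not that the
phenomenological generator is a faithful biophysical model of real
recordings.

One regime is flagged as an assumption: at the highest intensities,
sharpening saturates in real terminals; the generator's linear subtractive
inhibition does not saturate, so fixtures for that regime cap the
inhibition capacity explicitly rather than emerging from the model.

## Numerical conventions and degenerate inputs

* Seconds everywhere, `t = 0` at recording start; odor timing carried by
  `odor_pulse_spec()`. Frames map to time via the arena frame rate with
  frame 1 at `t = 0`.
* Every stochastic generator takes an integer seed and restores the
  caller's RNG state; identical seeds give byte-identical outputs.
* `decay_time()` interpolates; sharpness lookups use nearest samples (see
  above). Ties at the peak go to the first sample.
* Degenerate fits: constant traces return zero amplitudes and the mean as
  offset; single-exponential inputs are fitted with vanishing residual (the
  two-component parameterization is then not unique, so parameters are not
  interpreted, only the baseline).
* Zero references make sharpness undefined — an error, not a sentinel —
  whereas an unreachable decay threshold returns `NA`.

## Verification scale

The package verifies itself on deliberately desk-scale problems: 8–20 s
single-trial traces at native frame rates, 10 s extracellular records,
populations of 3–50 flies over 2–12 s, 200–500 Monte-Carlo replicates for
calibration checks. These sizes make every property cheap to re-run while
leaving the estimators in their intended operating regimes.

## A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- read_scenario_config(
  system.file("extdata", "demo_scenario.yaml", package = "olfcontrast")
)
run_physiology(cfg)
```

The result has one row per dilution × genotype with the in-pulse peak dF/F
and both sharpness variants; joint kernel blockade (`both_off`) shows larger
peaks and smaller sharpness than `control` at the supra-threshold dilution —
the gain-control and contrast-enhancement signature the statistics are
designed to expose.
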