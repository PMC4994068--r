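# olfcontrast

Temporal contrast analysis of olfactory sensory neuron (OSN) responses and
odor-driven behavior in *Drosophila*-style experiments.

Intense odor pulses leave peripheral OSNs firing for seconds after the
stimulus ends, and the odor itself lingers a few centimeters away from its
source. Presynaptic inhibition at the OSN axon terminals — fast GABA-A plus
slow GABA-B receptor signalling — truncates that sustained activity, so the
terminals report odor *offset* much more crisply than the periphery does.
This package provides the quantification chain for that phenomenon, for
experimenters analysing voltage/calcium imaging, single-sensillum
recordings, or arena tracking data, and for anyone who wants a fully
synthetic, seeded testbed of such recordings.

## The statistics at the core

For a response trace $x(t)$ and odor offset $t_\mathrm{off}$, the sharpness
coefficient with postpulse delay $\Delta$ (1.5 s by default) is

$$\mathrm{sharpness} = \frac{\mathrm{ref} - x(t_\mathrm{off}+\Delta)}{\mathrm{ref}}$$

with $\mathrm{ref} = \max_{t \in \mathrm{pulse}} x(t)$ for
`sharpness_max()` and $\mathrm{ref} = x(t_\mathrm{off})$ for
`sharpness_offset()`. A coefficient of 1 is full temporal contrast (back to
baseline 1.5 s after the pulse), 0 is none (activity still at its
reference). `decay_time()` reports the time a trace takes to fall from its
peak to 36.8% (1/e) of the peak, the standard summary of how slowly an odor
pulse decays at a given distance from its source.

Around these sit the supporting modules:

- **Preprocessing** — `roi_average()`, `fit_bleach()` (double-exponential
  photobleaching baseline), `detrend()`, `boxcar()` (eight rounds by
  default), `dff()`; `process_trace()` chains them.
- **Spikes** — `bandpass()` (300 Hz–2 kHz zero-phase), `detect_spikes()`
  (MAD threshold), `sort_units()` (deterministic 1-D 2-means),
  `firing_rate()`, `postpulse_comparison()`.
- **Behavior** — `kalman_track()` (constant-velocity filter, greedy gated
  assignment), `delta_d()` ($\Delta d_t = d_0 - d_t$, positive = toward the
  port), `mean_distance_timecourse()` (0.5 s bins), `radial_velocity()`,
  `postpulse_kinetics()` (3 cm initial-distance strata),
  `net_displacement()`.
- **Synthetic data** — `make_odor_pulse()`, `arena_pid()`, `osn_rate()`,
  `apply_presynaptic_inhibition()`, `sample_spikes()`,
  `render_extracellular()`, `render_arclight()`, `render_gcamp()`,
  `render_movie()`, `simulate_flies()`; all seeded and deterministic.
- **Pipeline** — `scenario_config()` / `read_scenario_config()` (YAML),
  `run_physiology()`, `run_behavior()`.

See the vignette `vignettes/temporal-contrast-methods.Rmd` for the model
assumptions, parameter meanings and design choices.

## Worked example

Simulate a supra-threshold 1 s odor pulse, drive the OSN rate model, apply
presynaptic inhibition at the terminals, render a noisy voltage-indicator
fluorescence trace on a bleaching baseline, preprocess it, and compare the
temporal contrast of the terminal signal with the peripheral firing rate:

```r
library(olfcontrast)

pulse <- odor_pulse_spec(onset_s = 2, duration_s = 1, peak = 1,
                         dilution_label = "1:5")
pid <- make_odor_pulse(pulse, total_s = 20, sample_rate = 125)
rate <- osn_rate(pid, osn_params())                       # peripheral rate, Hz
terminal <- apply_presynaptic_inhibition(rate, inhibition_params())
bleach <- bleach_model(30, 15, 4, 60, 100)
fluor <- render_arclight(terminal, bleach, scale = -0.05, drive_ref = 100,
                         noise_sd = 0.03, seed = 1)
resp <- process_trace(fluor, baseline_window = c(0, 1.7),
                      exclude_window = c(1.8, 13), invert = TRUE)

sharpness_offset(resp, offset_time = 3)   # terminal voltage signal
#> # A tibble: 1 × 5
#>   variant reference_value post_value delay_s coefficient
#>   <chr>             <dbl>      <dbl>   <dbl>       <dbl>
#> 1 offset             1.19     0.0726     1.5       0.939

sharpness_offset(rate, offset_time = 3)   # peripheral firing rate
#> # A tibble: 1 × 5
#>   variant reference_value post_value delay_s coefficient
#>   <chr>             <dbl>      <dbl>   <dbl>       <dbl>
#> 1 offset             52.8       16.6     1.5       0.686
```

The inhibited terminal signal has lost almost all of its activity 1.5 s
after odor offset (coefficient 0.94 — high temporal contrast), while the
peripheral rate still sustains a third of its offset value (0.69): the
contrast enhancement the coefficient is built to expose. The same pulse
measured at increasing distance from an arena odor port decays ever more
slowly:

```r
decay_time(arena_pid(2, pulse))   # 2 cm from the port
#> [1] 0.1149615
decay_time(arena_pid(5, pulse))   # 5 cm from the port
#> [1] 1.184679
```

so a fly more than 3–4 cm away experiences only a gradual offset — which is
why the behavioral kinetics (`postpulse_kinetics()`) stratify flies by
initial distance at 3 cm.

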