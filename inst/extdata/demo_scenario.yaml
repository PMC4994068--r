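# Demo physiology scenario: two gas-phase dilutions straddling the
# sustained-firing threshold, control vs joint GABA-receptor knockdown.
scenario: physiology
dilutions:
  "1:25": 0.3
  "1:5": 1.0
genotypes: [control, both_off]
pulse: {onset_s: 2, duration_s: 1, peak: 1, rise_tau_s: 0.05, decay_tau_s: 0.1}
bleach: {a_fast: 30, a_slow: 15, tau_fast_s: 4, tau_slow_s: 60, offset: 100}
noise_sd: 0.02
seed: 3
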