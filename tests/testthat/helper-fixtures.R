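# shared fixtures, all generated in code

# uniform local odor field: no distance dependence, used when a test must
# isolate a behavioral parameter from odor-lingering physics
identity_profile <- function(distance_cm) {
  list(peak_factor = 1, tau_factor = 1)
}

# the standard sustained-response fixture: 1 s pulse at supra-threshold
# intensity, OSN rate with sustained postpulse firing
fixture_sustained <- function(total_s = 8, sample_rate = 125) {
  spec <- odor_pulse_spec(onset_s = 2, duration_s = 1, peak = 1)
  pid <- make_odor_pulse(spec, total_s, sample_rate)
  list(spec = spec, pid = pid, rate = osn_rate(pid, osn_params()),
       offset_s = 3)
}

# two-unit spike trains with 2:1 amplitudes; spikes of the smaller unit
# falling within `min_sep_s` of a larger-unit spike are dropped so the
# extracellular render contains no overlapping templates
fixture_two_unit_trains <- function(rate, seed_a = 11, seed_b = 22,
                                    min_sep_s = 0.003) {
  train_a <- sample_spikes(rate, seed = seed_a, unit_label = "A", amplitude = 2)
  rate_b <- rate
  rate_b$value <- 0.6 * rate$value
  train_b <- sample_spikes(rate_b, seed = seed_b, unit_label = "B", amplitude = 1)
  keep <- vapply(train_b$time_s, function(tt) {
    all(abs(train_a$time_s - tt) > min_sep_s)
  }, logical(1))
  list(A = train_a, B = train_b[keep, ])
}

# detection recall/precision against planted spike times (1.5 ms tolerance)
match_events <- function(event_times, truth_times, tol_s = 0.0015) {
  recall <- mean(vapply(truth_times, function(tt) {
    any(abs(event_times - tt) < tol_s)
  }, logical(1)))
  precision <- if (length(event_times)) {
    mean(vapply(event_times, function(tt) {
      any(abs(truth_times - tt) < tol_s)
    }, logical(1)))
  } else {
    NA_real_
  }
  list(recall = recall, precision = precision)
}
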