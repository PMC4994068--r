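#' Synthesize a PID odor-pulse waveform
#'
#' A solenoid-valve odor pulse as read out by a photoionization detector:
#' zero baseline before onset, first-order rise toward `peak` while the valve
#' is open, first-order decay after it closes.
#'
#' @param spec An [odor_pulse_spec()].
#' @param total_s Total trace duration, seconds; must cover onset + duration.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return A trace tibble (`time_s`, `value`) in PID units.
#' @export
#' @examples
#' pid <- make_odor_pulse(odor_pulse_spec(onset_s = 1, duration_s = 1), 6, 125)
make_odor_pulse <- function(spec, total_s, sample_rate = 125) {
  stopifnot(inherits(spec, "odor_pulse_spec"))
  if (sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  offset_s <- spec$onset_s + spec$duration_s
  if (total_s < offset_s) {
    stop("`total_s` must cover the pulse (onset + duration)", call. = FALSE)
  }
  t <- seq(0, total_s, by = 1 / sample_rate)
  v <- numeric(length(t))
  if (spec$duration_s > 0) {
    during <- t >= spec$onset_s & t < offset_s
    v[during] <- spec$peak * (1 - exp(-(t[during] - spec$onset_s) / spec$rise_tau_s))
    v_off <- spec$peak * (1 - exp(-spec$duration_s / spec$rise_tau_s))
    after <- t >= offset_s
    v[after] <- v_off * exp(-(t[after] - offset_s) / spec$decay_tau_s)
  }
  tibble::tibble(time_s = t, value = v)
}

#' Distance-dependent odor-pulse profile inside the arena
#'
#' Maps distance from the odor port to the local pulse peak and decay time
#' constant. Near the port the pulse is sharp and strong; the decay time
#' constant rises steeply beyond 3-4 cm, where the odor lingers and
#' concentration changes only gradually.
#'
#' @param peak_length_cm Length constant of the peak attenuation, cm.
#' @param tau_scale Factor by which the decay tau has grown far from the
#'   port relative to the port itself.
#' @param tau_midpoint_cm Distance at which the tau increase is half
#'   complete, cm.
#' @param tau_steepness_cm Width of the tau transition, cm.
#'
#' @return A function `distance_cm -> list(peak_factor, tau_factor)` suitable
#'   for [arena_pid()].
#' @export
arena_decay_profile <- function(peak_length_cm = 4, tau_scale = 12,
                                tau_midpoint_cm = 3.5, tau_steepness_cm = 0.35) {
  force(peak_length_cm); force(tau_scale)
  force(tau_midpoint_cm); force(tau_steepness_cm)
  function(distance_cm) {
    list(
      peak_factor = exp(-distance_cm / peak_length_cm),
      tau_factor = 1 + (tau_scale - 1) /
        (1 + exp(-(distance_cm - tau_midpoint_cm) / tau_steepness_cm))
    )
  }
}

#' PID waveform at a given distance from the odor port
#'
#' Rescales an odor pulse by a distance profile: the peak is non-increasing
#' and the postpulse decay time constant non-decreasing in distance.
#'
#' @param distance_cm Distance from the odor port, cm (0 to the arena
#'   diameter, 10 cm).
#' @param spec The [odor_pulse_spec()] at the port.
#' @param profile A profile function as returned by [arena_decay_profile()];
#'   the default identity at distance 0.
#' @param total_s,sample_rate Passed to [make_odor_pulse()].
#'
#' @return A trace tibble in PID units.
#' @export
arena_pid <- function(distance_cm, spec, profile = arena_decay_profile(),
                      total_s = spec$onset_s + spec$duration_s + 6,
                      sample_rate = 125) {
  if (distance_cm < 0 || distance_cm > 10) {
    stop("`distance_cm` must lie within the 10 cm arena diameter", call. = FALSE)
  }
  fac <- profile(distance_cm)
  local_spec <- odor_pulse_spec(
    onset_s = spec$onset_s, duration_s = spec$duration_s,
    peak = spec$peak * fac$peak_factor,
    rise_tau_s = spec$rise_tau_s,
    decay_tau_s = spec$decay_tau_s * fac$tau_factor,
    dilution_label = spec$dilution_label
  )
  make_odor_pulse(local_spec, total_s, sample_rate)
}
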