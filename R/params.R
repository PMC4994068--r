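#' Odor pulse specification
#'
#' Describes one square odor command shaped by the delivery system into a
#' first-order rise during the pulse and a first-order decay after valve
#' closure, as seen on a photoionization detector (PID) at the outlet.
#'
#' @param onset_s Pulse onset, seconds.
#' @param duration_s Commanded pulse duration, seconds (>= 0).
#' @param peak Asymptotic PID amplitude, arbitrary units (> 0).
#' @param rise_tau_s Rise time constant, seconds (> 0).
#' @param decay_tau_s Decay time constant after offset, seconds (> 0).
#' @param dilution_label Free-text gas-phase dilution label, e.g. `"1:5"`.
#'
#' @return A list of class `odor_pulse_spec`.
#' @export
odor_pulse_spec <- function(onset_s = 1, duration_s = 1, peak = 1,
                            rise_tau_s = 0.05, decay_tau_s = 0.1,
                            dilution_label = "1:5") {
  stopifnot(duration_s >= 0)
  if (peak <= 0) stop("`peak` must be positive", call. = FALSE)
  if (rise_tau_s <= 0 || decay_tau_s <= 0) {
    stop("rise and decay time constants must be positive", call. = FALSE)
  }
  structure(
    list(
      onset_s = onset_s, duration_s = duration_s, peak = peak,
      rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
      dilution_label = dilution_label
    ),
    class = "odor_pulse_spec"
  )
}

#' Olfactory sensory neuron rate-model parameters
#'
#' Phenomenological firing-rate model of a peripheral OSN: spontaneous rate,
#' concentration gain with first-order adaptation, a threshold-gated slow
#' component producing sustained postpulse firing at high odor intensities,
#' and poststimulus inhibition (rate dips below spontaneous after weak
#' pulses).
#'
#' @param r_spont Spontaneous rate, Hz (>= 0).
#' @param gain Rate gain, Hz per PID unit.
#' @param adapt_tau_s Adaptation time constant, seconds.
#' @param adapt_depth Fractional steady-state adaptation, in \[0, 1\].
#' @param sustain_threshold PID amplitude above which the sustained component
#'   charges. Placed between the amplitudes of weak (1:25) and strong (1:5)
#'   dilutions.
#' @param sustain_gain Sustained rate per PID unit above threshold, Hz.
#' @param sustain_decay_s Decay time constant of sustained firing after
#'   odor offset, seconds.
#' @param inhib_depth Poststimulus inhibition depth, Hz.
#' @param inhib_tau_s Poststimulus inhibition decay time constant, seconds.
#'
#' @return A list of class `osn_params`.
#' @export
osn_params <- function(r_spont = 8, gain = 60, adapt_tau_s = 0.4,
                       adapt_depth = 0.5, sustain_threshold = 0.5,
                       sustain_gain = 25, sustain_decay_s = 4,
                       inhib_depth = 6, inhib_tau_s = 1) {
  stopifnot(
    r_spont >= 0, adapt_tau_s > 0, adapt_depth >= 0, adapt_depth <= 1,
    sustain_decay_s > 0, inhib_depth >= 0, inhib_tau_s > 0
  )
  structure(
    list(
      r_spont = r_spont, gain = gain, adapt_tau_s = adapt_tau_s,
      adapt_depth = adapt_depth, sustain_threshold = sustain_threshold,
      sustain_gain = sustain_gain, sustain_decay_s = sustain_decay_s,
      inhib_depth = inhib_depth, inhib_tau_s = inhib_tau_s
    ),
    class = "osn_params"
  )
}

#' Presynaptic inhibition parameters
#'
#' Two rate-driven subtractive inhibition kernels acting on OSN terminal
#' activity: a fast one standing for ionotropic GABA-A receptor conductances
#' and a slow one for metabotropic GABA-B signalling. Each kernel is a causal
#' unit-area exponential; either can be disabled to emulate receptor
#' blockade or knockdown.
#'
#' @param gA_weight,gB_weight Dimensionless kernel weights (>= 0).
#' @param gA_tau_s,gB_tau_s Kernel time constants, seconds; the fast (A)
#'   kernel must be faster than the slow (B) kernel.
#' @param gA_enabled,gB_enabled Logical flags emulating receptor blockade.
#'
#' @return A list of class `inhibition_params`.
#' @export
inhibition_params <- function(gA_weight = 0.25, gA_tau_s = 0.1,
                              gB_weight = 0.35, gB_tau_s = 1.5,
                              gA_enabled = TRUE, gB_enabled = TRUE) {
  stopifnot(gA_weight >= 0, gB_weight >= 0, gA_tau_s > 0, gB_tau_s > 0)
  if (gA_tau_s >= gB_tau_s) {
    stop("the fast kernel must have `gA_tau_s` < `gB_tau_s`", call. = FALSE)
  }
  structure(
    list(
      gA_weight = gA_weight, gA_tau_s = gA_tau_s,
      gB_weight = gB_weight, gB_tau_s = gB_tau_s,
      gA_enabled = isTRUE(gA_enabled), gB_enabled = isTRUE(gB_enabled)
    ),
    class = "inhibition_params"
  )
}

#' Double-exponential photobleaching baseline
#'
#' Baseline model `b(t) = a_fast exp(-t/tau_fast_s) + a_slow exp(-t/tau_slow_s)
#' + offset` describing rapid plus slow photobleaching of indicator
#' fluorescence.
#'
#' @param a_fast,a_slow Component amplitudes, arbitrary units.
#' @param tau_fast_s,tau_slow_s Time constants, seconds, `tau_fast_s <
#'   tau_slow_s`.
#' @param offset Asymptotic fluorescence, arbitrary units.
#'
#' @return A list of class `bleach_model`.
#' @export
bleach_model <- function(a_fast, a_slow, tau_fast_s, tau_slow_s, offset) {
  stopifnot(tau_fast_s > 0, tau_slow_s > 0)
  if (tau_fast_s >= tau_slow_s) {
    stop("`tau_fast_s` must be smaller than `tau_slow_s`", call. = FALSE)
  }
  structure(
    list(
      a_fast = a_fast, a_slow = a_slow,
      tau_fast_s = tau_fast_s, tau_slow_s = tau_slow_s, offset = offset
    ),
    class = "bleach_model"
  )
}

#' Evaluate a bleach baseline
#'
#' @param model A [bleach_model()].
#' @param t Times in seconds.
#' @return Baseline values at `t`.
#' @export
bleach_baseline <- function(model, t) {
  model$a_fast * exp(-t / model$tau_fast_s) +
    model$a_slow * exp(-t / model$tau_slow_s) +
    model$offset
}

#' Circular-arena geometry and recording configuration
#'
#' A 10 cm diameter circular arena with four odor ports on the boundary at
#' 90 degree spacing, filmed at 30 frames per second. Coordinates are in cm
#' with the origin at the arena center.
#'
#' @param radius_cm Arena radius, cm. Default 5.
#' @param n_ports Number of equally spaced boundary ports. Default 4.
#' @param active_port Index (1-based) of the odorized port.
#' @param frame_rate Video frame rate, frames per second.
#' @param metadata Free-text environment metadata (temperature, humidity).
#'
#' @return A list of class `arena_config` with a `port_positions` matrix
#'   (columns `x_cm`, `y_cm`).
#' @export
arena_config <- function(radius_cm = 5, n_ports = 4, active_port = 1,
                         frame_rate = 30, metadata = NULL) {
  stopifnot(radius_cm > 0, frame_rate > 0, n_ports >= 1)
  if (active_port < 1 || active_port > n_ports) {
    stop("`active_port` must index one of the ports", call. = FALSE)
  }
  ang <- 2 * pi * (seq_len(n_ports) - 1) / n_ports
  ports <- cbind(x_cm = radius_cm * cos(ang), y_cm = radius_cm * sin(ang))
  structure(
    list(
      radius_cm = radius_cm, port_positions = ports,
      active_port = as.integer(active_port), frame_rate = frame_rate,
      metadata = metadata
    ),
    class = "arena_config"
  )
}

#' Fly locomotion parameters
#'
#' Random-walk-with-drift kinematics: flies move at a base speed with
#' diffusing heading and acquire a radial drift toward (positive) or away
#' from (negative) the active odor port, with magnitude set by
#' `drift_gain(c)` evaluated at the local odor concentration. The drift
#' responds with a sensing latency and can outlast the local concentration
#' decline (`persistence_s`), which is what produces postpulse avoidance
#' that persists after the odor is gone.
#'
#' @param base_speed Undirected walking speed, cm/s (>= 0).
#' @param heading_diffusion Heading diffusion coefficient, rad^2/s.
#' @param drift_gain Function mapping local concentration (PID units) to a
#'   signed radial drift speed in cm/s; positive = toward the port.
#' @param persistence_s Seconds the drift persists beyond the local
#'   concentration decline (>= 0).
#' @param sensing_latency_s Sensing delay, seconds.
#'
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(base_speed = 1.0, heading_diffusion = 2,
                            drift_gain = function(c) 0.8 * c * (c <= 0.5) - 1.2 * c * (c > 0.5),
                            persistence_s = 0, sensing_latency_s = 0.1) {
  stopifnot(base_speed >= 0, persistence_s >= 0, sensing_latency_s >= 0)
  stopifnot(is.function(drift_gain))
  structure(
    list(
      base_speed = base_speed, heading_diffusion = heading_diffusion,
      drift_gain = drift_gain, persistence_s = persistence_s,
      sensing_latency_s = sensing_latency_s
    ),
    class = "behavior_params"
  )
}
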