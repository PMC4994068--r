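#' Phenomenological OSN firing-rate response to an odor waveform
#'
#' Integrates a rate model on the PID time grid:
#' `r(t) = max(0, r_spont + gain * a(t) * c(t) + S(t) - I(t))`, where
#' `a(t)` is first-order adaptation relaxing from 1 toward
#' `1 - adapt_depth` while the stimulus is on, `S(t)` is a threshold-gated
#' sustained component that charges when the concentration exceeds
#' `sustain_threshold` and decays with `sustain_decay_s` after offset
#' (sustained postpulse firing at high odor intensity), and `I(t)` is
#' poststimulus inhibition injected at stimulus offset whenever the sustained
#' component is inactive (rate dips below spontaneous after weak pulses).
#'
#' @param pid A nonnegative PID trace tibble (see [make_odor_pulse()]).
#' @param p An [osn_params()] object.
#' @param sustain_charge_s Charging time constant of the sustained component
#'   while the stimulus is above threshold, seconds.
#'
#' @return A rate trace tibble in Hz.
#' @export
osn_rate <- function(pid, p, sustain_charge_s = 0.2) {
  stopifnot(inherits(p, "osn_params"))
  pid <- as_trace(pid)
  if (any(pid$value < 0)) stop("PID trace must be nonnegative", call. = FALSE)
  c_t <- pid$value
  n <- length(c_t)
  dt <- if (n > 1) stats::median(diff(pid$time_s)) else 1
  eps <- 1e-3 * max(c_t, 1e-12)
  stim <- c_t > eps

  sustained_regime <- max(c_t) >= p$sustain_threshold

  a <- numeric(n); a[1] <- 1
  s <- numeric(n)
  inh <- numeric(n)
  for (i in seq_len(n - 1)) {
    a_target <- if (stim[i]) 1 - p$adapt_depth else 1
    a[i + 1] <- a[i] + dt * (a_target - a[i]) / p$adapt_tau_s

    s_target <- p$sustain_gain * max(0, c_t[i] - p$sustain_threshold)
    s_tau <- if (s_target > s[i]) sustain_charge_s else p$sustain_decay_s
    s[i + 1] <- s[i] + dt * (s_target - s[i]) / s_tau

    inh[i + 1] <- inh[i] * exp(-dt / p$inhib_tau_s)
    # falling stimulus edge with no sustained activity: poststimulus inhibition
    if (stim[i] && !stim[i + 1] && !sustained_regime) {
      inh[i + 1] <- inh[i + 1] + p$inhib_depth
    }
  }
  r <- pmax(0, p$r_spont + p$gain * a * c_t + s - inh)
  tibble::tibble(time_s = pid$time_s, value = r)
}

# internal: causal unit-area exponential kernel convolution on a uniform grid
exp_kernel_filter <- function(x, tau_s, dt) {
  n_k <- max(2L, ceiling(6 * tau_s / dt))
  k <- exp(-(seq_len(n_k) - 1) * dt / tau_s)
  k <- k / (sum(k) * dt)
  out <- stats::convolve(c(x, numeric(n_k - 1)), rev(k), type = "open")
  out[seq_along(x)] * dt
}

#' Apply presynaptic inhibition to a rate trace
#'
#' Subtracts two rate-driven inhibitory signals from the input: each is the
#' input convolved with a causal unit-area exponential kernel (fast "A",
#' slow "B") scaled by its weight. The output is clamped at zero, so
#' inhibition never increases the signal and never drives it negative.
#' Disabling both kernels emulates joint receptor blockade and returns the
#' uninhibited input.
#'
#' @param rate A nonnegative rate trace tibble, Hz.
#' @param q An [inhibition_params()] object.
#'
#' @return A rate trace tibble, Hz.
#' @export
apply_presynaptic_inhibition <- function(rate, q) {
  stopifnot(inherits(q, "inhibition_params"))
  rate <- as_trace(rate)
  if (any(rate$value < 0)) stop("rate trace must be nonnegative", call. = FALSE)
  dt <- 1 / trace_sample_rate(rate)
  i_total <- numeric(nrow(rate))
  if (q$gA_enabled && q$gA_weight > 0) {
    i_total <- i_total + q$gA_weight * exp_kernel_filter(rate$value, q$gA_tau_s, dt)
  }
  if (q$gB_enabled && q$gB_weight > 0) {
    i_total <- i_total + q$gB_weight * exp_kernel_filter(rate$value, q$gB_tau_s, dt)
  }
  tibble::tibble(time_s = rate$time_s, value = pmax(0, rate$value - i_total))
}

#' Sample a spike train from a rate trace
#'
#' Inhomogeneous Poisson process by thinning, with an absolute refractory
#' period enforced afterwards. Deterministic for a fixed seed.
#'
#' @param rate A nonnegative rate trace tibble, Hz.
#' @param refractory_s Absolute refractory period, seconds.
#' @param seed Integer RNG seed.
#' @param unit_label Label stored with the train.
#' @param amplitude Nominal spike amplitude, arbitrary units.
#'
#' @return A spike-train tibble with columns `unit`, `time_s`, `amplitude`,
#'   times strictly increasing.
#' @export
sample_spikes <- function(rate, refractory_s = 0.002, seed = 1,
                          unit_label = "A", amplitude = 1) {
  rate <- as_trace(rate)
  if (any(rate$value < 0)) stop("rate trace must be nonnegative", call. = FALSE)
  r_max <- max(rate$value)
  t0 <- rate$time_s[1]
  t1 <- rate$time_s[nrow(rate)]
  times <- with_seed(seed, {
    if (r_max <= 0 || t1 <= t0) {
      numeric(0)
    } else {
      n_cand <- stats::rpois(1, r_max * (t1 - t0))
      cand <- sort(stats::runif(n_cand, t0, t1))
      fs <- trace_sample_rate(rate)
      idx <- pmin(nrow(rate), pmax(1, round((cand - t0) * fs) + 1))
      keep <- stats::runif(n_cand) < rate$value[idx] / r_max
      accepted <- cand[keep]
      out <- numeric(0)
      last <- -Inf
      for (tt in accepted) {
        if (tt - last >= refractory_s) {
          out <- c(out, tt)
          last <- tt
        }
      }
      out
    }
  })
  tibble::tibble(
    unit = rep(unit_label, length(times)),
    time_s = times,
    amplitude = rep(amplitude, length(times))
  )
}
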