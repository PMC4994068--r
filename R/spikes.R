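#' Zero-phase band-pass filter for extracellular recordings
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), the digital equivalent of the 300 Hz - 2 kHz
#' analog band used for single-sensillum recordings. DC is fully removed.
#'
#' @param raw A raw trace tibble (typically 10 kHz).
#' @param lo,hi Band edges, Hz. Defaults 300 and 2000.
#' @param order Butterworth order per pass. Default 3.
#'
#' @return A filtered trace tibble.
#' @export
bandpass <- function(raw, lo = 300, hi = 2000, order = 3) {
  raw <- as_trace(raw)
  fs <- trace_sample_rate(raw)
  if (hi >= fs / 2 || lo <= 0 || lo >= hi) {
    stop("band must satisfy 0 < lo < hi < Nyquist (", fs / 2, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  # the passband excludes DC, so remove the mean up front: this makes DC
  # rejection exact and shrinks the startup transient the IIR state causes
  x <- raw$value - mean(raw$value)
  n <- length(x)
  p <- min(n - 1, max(32L, round(3 * fs / lo)))
  padded <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, padded))[(p + 1):(p + n)]
  tibble::tibble(time_s = raw$time_s, value = y)
}

#' Threshold spike detection on a filtered trace
#'
#' Detects events where the absolute signal exceeds `k_mad` times the median
#' absolute deviation of the trace (a robust noise estimate that tolerates
#' spike contamination). Each event is timed at the local absolute extremum
#' within 1 ms of the threshold crossing; events closer than the refractory
#' period are suppressed keeping the larger-amplitude one.
#'
#' @param filtered A band-passed trace tibble.
#' @param k_mad Threshold in MAD units. Default 5.
#' @param refractory_ms Minimum event spacing, milliseconds. Default 2.
#'
#' @return A tibble of events: `time_s`, `amplitude` (absolute extremum
#'   value, a.u.), sorted by time.
#' @export
detect_spikes <- function(filtered, k_mad = 5, refractory_ms = 2) {
  filtered <- as_trace(filtered)
  if (nrow(filtered) == 0) stop("empty trace", call. = FALSE)
  v <- filtered$value
  fs <- trace_sample_rate(filtered)
  thr <- k_mad * stats::mad(v)
  empty <- tibble::tibble(time_s = numeric(0), amplitude = numeric(0))
  if (thr <= 0 || !any(abs(v) > thr)) return(empty)

  above <- abs(v) > thr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  half <- round(0.001 * fs)
  cand_idx <- vapply(onsets, function(i) {
    win <- i:min(length(v), i + half)
    win[which.max(abs(v[win]))]
  }, integer(1))
  cand_idx <- unique(cand_idx)
  cand <- tibble::tibble(
    idx = cand_idx,
    time_s = filtered$time_s[cand_idx],
    amplitude = abs(v[cand_idx])
  )

  # refractory suppression, larger amplitude wins
  cand <- cand[order(-cand$amplitude, cand$time_s), ]
  refr <- refractory_ms / 1000
  kept_times <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!length(kept_times) || min(abs(kept_times - cand$time_s[i])) >= refr) {
      keep[i] <- TRUE
      kept_times <- c(kept_times, cand$time_s[i])
    }
  }
  out <- cand[keep, c("time_s", "amplitude")]
  dplyr::arrange(out, .data$time_s)
}

#' Sort detected events into amplitude classes
#'
#' One-dimensional 2-means clustering of event amplitudes with deterministic
#' initialization at the 25th and 75th percentiles. The larger-amplitude
#' cluster is labeled `"A"` (the convention for the larger spike in a
#' two-neuron sensillum), the other `"B"`. With fewer events than units, or
#' amplitudes that do not separate, all events fall back to a single unit
#' with a warning.
#'
#' @param events An event tibble from [detect_spikes()].
#' @param n_units Number of amplitude classes. Default 2.
#'
#' @return A spike-train tibble (`unit`, `time_s`, `amplitude`).
#' @export
sort_units <- function(events, n_units = 2) {
  stopifnot(all(c("time_s", "amplitude") %in% names(events)))
  amp <- events$amplitude
  single <- function(msg) {
    warning(msg, call. = FALSE)
    tibble::tibble(unit = rep("A", length(amp)),
                   time_s = events$time_s, amplitude = amp)
  }
  if (length(amp) < n_units) return(single("fewer events than units; single-unit fallback"))
  centers <- stats::quantile(amp, probs = seq(0.25, 0.75, length.out = n_units),
                             names = FALSE, type = 7)
  if (diff(range(centers)) == 0) return(single("amplitudes do not separate; single-unit fallback"))
  for (iter in 1:100) {
    assign_u <- apply(abs(outer(amp, centers, "-")), 1, which.min)
    new_centers <- vapply(seq_len(n_units), function(k) {
      if (any(assign_u == k)) mean(amp[assign_u == k]) else centers[k]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  # label clusters by decreasing center amplitude: A, B, ...
  ord <- order(centers, decreasing = TRUE)
  labels <- LETTERS[seq_len(n_units)]
  unit <- labels[match(assign_u, ord)]
  out <- tibble::tibble(unit = unit, time_s = events$time_s, amplitude = amp)
  dplyr::arrange(out, .data$unit, .data$time_s)
}

#' Sliding-window firing-rate estimate
#'
#' Counts spikes in a rectangular window slid along the recording
#' (count / window length, Hz); a Gaussian kernel estimate is available as an
#' alternative.
#'
#' @param train A spike-train tibble (or anything with a `time_s` column).
#' @param window_s Window length, seconds. Default 0.1.
#' @param step_s Grid step, seconds. Default 0.008.
#' @param span `c(start_s, end_s)` of the output grid; defaults to the spike
#'   range (0-padded to at least one window).
#' @param kernel `"rect"` (default) or `"gaussian"` (SD = `window_s / 2`).
#'
#' @return A rate trace tibble, Hz.
#' @export
firing_rate <- function(train, window_s = 0.1, step_s = 0.008, span = NULL,
                        kernel = c("rect", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(window_s > 0, step_s > 0)
  times <- train$time_s
  if (is.null(span)) {
    span <- if (length(times)) range(times) + c(-window_s, window_s) else c(0, window_s)
  }
  grid <- seq(span[1], span[2], by = step_s)
  v <- if (!length(times)) {
    numeric(length(grid))
  } else if (kernel == "rect") {
    vapply(grid, function(g) {
      sum(times >= g - window_s / 2 & times < g + window_s / 2) / window_s
    }, numeric(1))
  } else {
    sd_k <- window_s / 2
    vapply(grid, function(g) sum(stats::dnorm(times, g, sd_k)), numeric(1))
  }
  tibble::tibble(time_s = grid, value = v)
}

#' Spontaneous versus postpulse firing comparison
#'
#' Compares the mean rate in a pre-stimulus window with the rate 1.5 s after
#' odor pulse offset — the diagnostic for sustained postpulse firing (rate
#' above spontaneous after intense pulses) versus poststimulus inhibition
#' (rate below spontaneous after weak ones).
#'
#' @param rate A rate trace tibble, Hz.
#' @param pulse An [odor_pulse_spec()] (supplies the offset time).
#' @param delay_s Postpulse sampling delay, seconds. Default 1.5.
#' @param spont_window `c(start_s, end_s)` pre-stimulus window.
#'
#' @return A one-row tibble: `spont_hz`, `post_hz`, `delay_s`.
#' @export
postpulse_comparison <- function(rate, pulse, delay_s = 1.5,
                                 spont_window = c(0, pulse$onset_s)) {
  rate <- as_trace(rate)
  offset_s <- pulse$onset_s + pulse$duration_s
  rng <- range(rate$time_s)
  if (spont_window[1] < rng[1] - 1e-9 || offset_s + delay_s > rng[2] + 1e-9) {
    stop("comparison windows fall outside the rate trace", call. = FALSE)
  }
  in_spont <- rate$time_s >= spont_window[1] & rate$time_s <= spont_window[2]
  if (!any(in_spont)) stop("spontaneous window contains no samples", call. = FALSE)
  tibble::tibble(
    spont_hz = mean(rate$value[in_spont]),
    post_hz = trace_value_at(rate, offset_s + delay_s),
    delay_s = delay_s
  )
}
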