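sharpness_result <- function(variant, reference_value, post_value, delay_s) {
  tibble::tibble(
    variant = variant,
    reference_value = reference_value,
    post_value = post_value,
    delay_s = delay_s,
    coefficient = (reference_value - post_value) / reference_value
  )
}

#' Peak-referenced sharpness coefficient
#'
#' `(reference - post) / reference` with the reference being the maximum of
#' the trace over the stimulus window and the postpulse value sampled
#' `delay_s` after odor offset (nearest sample). A coefficient of 1 means the
#' response has fully returned to baseline 1.5 s after the pulse (100%
#' temporal contrast); 0 means the postpulse value still equals the in-pulse
#' maximum (no temporal contrast). Negative coefficients (postpulse value
#' above the reference) are reported, never clamped. The coefficient is
#' invariant under positive rescaling of the trace.
#'
#' @param trace A response trace tibble (percent dF/F or Hz).
#' @param offset_time Odor offset time, seconds.
#' @param delay_s Postpulse sampling delay, seconds. Default 1.5.
#' @param onset_time Start of the stimulus search window for the maximum;
#'   defaults to the trace start.
#'
#' @return A one-row tibble (`variant`, `reference_value`, `post_value`,
#'   `delay_s`, `coefficient`).
#' @export
sharpness_max <- function(trace, offset_time, delay_s = 1.5,
                          onset_time = NULL) {
  trace <- as_trace(trace)
  if (is.null(onset_time)) onset_time <- trace$time_s[1]
  in_win <- trace$time_s >= onset_time & trace$time_s <= offset_time
  if (!any(in_win)) stop("stimulus window contains no samples", call. = FALSE)
  ref <- max(trace$value[in_win])
  if (ref == 0) stop("reference (in-pulse maximum) is zero; sharpness undefined", call. = FALSE)
  post <- trace_value_at(trace, offset_time + delay_s)
  sharpness_result("max", ref, post, delay_s)
}

#' Offset-referenced sharpness coefficient
#'
#' As [sharpness_max()] but referenced to the trace value at odor offset
#' rather than the in-pulse maximum — the variant that discounts sensory
#' adaptation during the pulse. A trace retaining 80-90% of its offset value
#' 1.5 s later scores 0.1-0.2; one retaining 20-40% scores 0.6-0.8.
#'
#' @inheritParams sharpness_max
#' @return A one-row tibble as in [sharpness_max()].
#' @export
sharpness_offset <- function(trace, offset_time, delay_s = 1.5) {
  trace <- as_trace(trace)
  ref <- trace_value_at(trace, offset_time)
  if (ref == 0) stop("value at odor offset is zero; sharpness undefined", call. = FALSE)
  post <- trace_value_at(trace, offset_time + delay_s)
  sharpness_result("offset", ref, post, delay_s)
}

#' Time-resolved sharpness coefficient
#'
#' Evaluates the offset-referenced sharpness coefficient over a grid of
#' postpulse delays, showing when after odor offset contrast enhancement
#' acts.
#'
#' @inheritParams sharpness_offset
#' @param delays Numeric vector of postpulse delays, seconds.
#'
#' @return A trace tibble with `time_s` = delay and `value` = coefficient.
#' @export
sharpness_timecourse <- function(trace, offset_time, delays) {
  coefs <- vapply(delays, function(d) {
    sharpness_offset(trace, offset_time, delay_s = d)$coefficient
  }, numeric(1))
  tibble::tibble(time_s = delays, value = coefs)
}

#' Decay time to 36.8% of peak
#'
#' The time a trace takes to fall from its peak to 36.8% (1/e) of the peak
#' value — the tau statistic used to characterize how quickly the odor
#' stimulus decays at a given distance from the port. The crossing is
#' linearly interpolated between the straddling samples. Returns `NA` when
#' the threshold is never reached after the peak.
#'
#' @param trace A trace tibble.
#' @param threshold_frac Fraction of peak defining the crossing. Default
#'   0.368.
#'
#' @return Decay time in seconds, or `NA_real_`.
#' @export
decay_time <- function(trace, threshold_frac = 0.368) {
  trace <- as_trace(trace)
  i_peak <- which.max(trace$value)
  peak <- trace$value[i_peak]
  thr <- threshold_frac * peak
  post <- trace$value[i_peak:nrow(trace)]
  below <- which(post <= thr)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1) return(0)
  t_post <- trace$time_s[i_peak:nrow(trace)]
  # linear interpolation between the straddling samples
  t_cross <- t_post[j - 1] + (t_post[j] - t_post[j - 1]) *
    (post[j - 1] - thr) / (post[j - 1] - post[j])
  t_cross - trace$time_s[i_peak]
}
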