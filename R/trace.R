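#' Build a uniformly sampled trace
#'
#' The package represents every sampled signal (PID odor waveforms, firing
#' rates, raw fluorescence, percent dF/F) as a tibble with a `time_s` column
#' in seconds and a `value` column in context-dependent units. `new_trace()`
#' constructs one from a value vector and its sample rate.
#'
#' @param values Numeric vector of samples; must be finite and non-empty.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds. Default 0.
#'
#' @return A tibble with columns `time_s` and `value`.
#' @export
#' @examples
#' tr <- new_trace(sin(seq(0, 2 * pi, length.out = 100)), sample_rate = 50)
#' head(tr)
new_trace <- function(values, sample_rate, t0 = 0) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 1) stop("`values` must have length >= 1", call. = FALSE)
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  tibble::tibble(
    time_s = t0 + (seq_along(values) - 1) / sample_rate,
    value = values
  )
}

#' @rdname new_trace
#' @param trace A data frame with `time_s` and `value` columns.
#' @export
as_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_s", "value") %in% names(trace))) {
    stop("a trace needs `time_s` and `value` columns", call. = FALSE)
  }
  tibble::as_tibble(trace[c("time_s", "value")])
}

#' Sampling rate of a trace
#'
#' Inferred from the median spacing of `time_s`.
#'
#' @param trace A trace tibble (see [new_trace()]).
#' @return Sampling rate in Hz.
#' @export
trace_sample_rate <- function(trace) {
  trace <- as_trace(trace)
  if (nrow(trace) < 2) stop("cannot infer sample rate from a single sample", call. = FALSE)
  dt <- stats::median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) stop("non-increasing time axis", call. = FALSE)
  1 / dt
}

#' Nearest-sample lookup
#'
#' Returns the trace value at the sample whose time is closest to `t`
#' (earlier sample wins ties). Sharpness statistics use nearest-sample
#' lookup so they report values the recording actually contains.
#'
#' @param trace A trace tibble.
#' @param t Time(s) in seconds; must fall within the trace span.
#' @return Numeric vector of values, one per element of `t`.
#' @export
trace_value_at <- function(trace, t) {
  trace <- as_trace(trace)
  rng <- range(trace$time_s)
  dt <- if (nrow(trace) > 1) stats::median(diff(trace$time_s)) else 0
  if (any(t < rng[1] - dt / 2) || any(t > rng[2] + dt / 2)) {
    stop("lookup time outside trace span", call. = FALSE)
  }
  idx <- vapply(t, function(ti) which.min(abs(trace$time_s - ti)), integer(1))
  trace$value[idx]
}

#' Read and write trace CSVs
#'
#' Plain CSV with `time_s,value` headers, the on-disk interchange format for
#' all single traces.
#'
#' @param path File path.
#' @return `read_trace_csv()` returns a trace tibble.
#' @export
read_trace_csv <- function(path) {
  as_trace(utils::read.csv(path))
}

#' @rdname read_trace_csv
#' @param trace A trace tibble.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as_trace(trace), path, row.names = FALSE)
  invisible(path)
}

# internal: seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
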