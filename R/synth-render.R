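# internal: biphasic extracellular spike template, ~2 ms support, peak |1|
spike_template <- function(sample_rate, width_s = 0.002) {
  n <- max(4L, round(width_s * sample_rate))
  tt <- seq(0, width_s, length.out = n)
  w <- sin(2 * pi * tt / width_s) * sin(pi * tt / width_s)^2
  w / max(abs(w))
}

#' Render an extracellular voltage trace from spike trains
#'
#' Places a fixed biphasic template (about 2 ms support) at every spike time,
#' scaled by the per-spike amplitude, and adds white noise — the synthetic
#' counterpart of a bandpassed single-sensillum recording digitized at
#' 10 kHz.
#'
#' @param trains A spike-train tibble (`unit`, `time_s`, `amplitude`) or a
#'   list of them; amplitudes should be distinct across units if the trace is
#'   meant to be sortable.
#' @param total_s Trace duration, seconds.
#' @param noise_sd Additive Gaussian noise SD, arbitrary units.
#' @param sample_rate Sampling rate, Hz. Default 10000.
#' @param seed RNG seed for the noise.
#'
#' @return A trace tibble, arbitrary units.
#' @export
render_extracellular <- function(trains, total_s, noise_sd = 0,
                                 sample_rate = 10000, seed = 1) {
  if (is.list(trains) && !is.data.frame(trains)) {
    trains <- dplyr::bind_rows(trains)
  }
  t <- seq(0, total_s, by = 1 / sample_rate)
  v <- numeric(length(t))
  tmpl <- spike_template(sample_rate)
  if (nrow(trains) > 0) {
    if (any(trains$time_s < 0 | trains$time_s > total_s)) {
      stop("spike time outside the trace span", call. = FALSE)
    }
    for (i in seq_len(nrow(trains))) {
      i0 <- round(trains$time_s[i] * sample_rate) + 1
      idx <- i0:(i0 + length(tmpl) - 1)
      ok <- idx <= length(v)
      v[idx[ok]] <- v[idx[ok]] + trains$amplitude[i] * tmpl[ok]
    }
  }
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
  }
  tibble::tibble(time_s = t, value = v)
}

# internal: soft-saturating map, sat(x) -> x as sat_level -> Inf
soft_sat <- function(x, sat_level) {
  if (!is.finite(sat_level)) return(x)
  sat_level * (1 - exp(-x / sat_level))
}

#' Render a voltage-indicator fluorescence trace
#'
#' Fluorescence of a genetically encoded voltage indicator imaged at 125 Hz:
#' `F(t) = b(t) * (1 + scale * sat(drive / drive_ref)) + noise`, where `b(t)`
#' is a double-exponential photobleaching baseline and `sat` is a
#' soft-saturating map (identity as `sat_level -> Inf`). The default `scale`
#' is negative — the indicator dims on depolarization — and processed traces
#' are conventionally inverted on load so responses plot upward.
#'
#' @param drive A trace tibble of membrane-potential drive (e.g. an OSN rate).
#' @param scale Fractional fluorescence change per unit of normalized drive;
#'   negative by default.
#' @param sat_level Saturation level in normalized drive units; `Inf`
#'   disables saturation.
#' @param bleach A [bleach_model()].
#' @param noise_sd Additive noise SD, arbitrary units.
#' @param drive_ref Normalization constant for the drive (drive units);
#'   default 1, i.e. `drive` is already normalized.
#' @param frame_rate Imaging frame rate, Hz; the drive is resampled onto this
#'   grid by nearest sample. Default 125.
#' @param seed RNG seed for the noise.
#'
#' @return A trace tibble of raw fluorescence, arbitrary units.
#' @export
render_arclight <- function(drive, bleach, scale = -0.05, sat_level = Inf,
                            noise_sd = 0, drive_ref = 1, frame_rate = 125,
                            seed = 1) {
  stopifnot(inherits(bleach, "bleach_model"))
  drive <- as_trace(drive)
  t <- seq(drive$time_s[1], drive$time_s[nrow(drive)], by = 1 / frame_rate)
  d <- trace_value_at(drive, t) / drive_ref
  b <- bleach_baseline(bleach, t)
  if (any(b <= 0)) stop("bleach baseline must be positive over the trace", call. = FALSE)
  f <- b * (1 + scale * soft_sat(d, sat_level))
  if (noise_sd > 0) f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  tibble::tibble(time_s = t, value = f)
}

#' Render a calcium-indicator fluorescence trace
#'
#' Convolves a firing-rate trace with a double-exponential calcium impulse
#' kernel (rise `ca_rise_s`, decay `ca_decay_s`, peak normalized to 1) and
#' scales the result onto a photobleaching baseline exactly as
#' [render_arclight()] does, at a 40 Hz calcium-imaging frame rate. Calcium
#' responses are far more sustained than the underlying electrical events.
#'
#' @param rate A nonnegative rate trace tibble, Hz.
#' @param ca_rise_s,ca_decay_s Kernel time constants, seconds;
#'   `ca_decay_s > ca_rise_s`.
#' @param bleach A [bleach_model()].
#' @param scale Fractional fluorescence change per unit of normalized drive;
#'   positive for a calcium indicator.
#' @param sat_level,noise_sd,drive_ref,seed As in [render_arclight()].
#' @param frame_rate Imaging frame rate, Hz. Default 40.
#'
#' @return A trace tibble of raw fluorescence, arbitrary units.
#' @export
render_gcamp <- function(rate, bleach, ca_rise_s = 0.05, ca_decay_s = 0.5,
                         scale = 0.2, sat_level = Inf, noise_sd = 0,
                         drive_ref = 1, frame_rate = 40, seed = 1) {
  if (ca_decay_s <= ca_rise_s) {
    stop("`ca_decay_s` must exceed `ca_rise_s`", call. = FALSE)
  }
  rate <- as_trace(rate)
  dt <- 1 / trace_sample_rate(rate)
  kt <- seq(0, ca_decay_s * 8, by = dt)
  k <- exp(-kt / ca_decay_s) - exp(-kt / ca_rise_s)
  k <- k / max(k)
  conv <- stats::convolve(c(rate$value, numeric(length(k) - 1)), rev(k),
                          type = "open")
  ca <- conv[seq_len(nrow(rate))] * dt
  drive <- tibble::tibble(time_s = rate$time_s, value = ca)
  render_arclight(drive, bleach,
    scale = scale, sat_level = sat_level, noise_sd = noise_sd,
    drive_ref = drive_ref, frame_rate = frame_rate, seed = seed
  )
}

#' Render an imaging movie from a trace
#'
#' Expands a fluorescence trace into a multi-frame grayscale stack on a small
#' camera chip: pixels inside the ROI mask carry the trace value plus
#' independent pixel noise, pixels outside carry a (bleached) background plus
#' noise.
#'
#' @param trace A fluorescence trace tibble.
#' @param roi_mask Logical matrix marking ROI pixels; must be nonempty.
#' @param grid Chip size `c(rows, cols)`; default 80 x 80. Ignored when
#'   `roi_mask` is supplied with its own dimensions.
#' @param background Background value, a.u., or a vector per frame.
#' @param pixel_noise_sd Independent per-pixel noise SD, a.u.
#' @param seed RNG seed.
#'
#' @return A numeric array `frames x rows x cols`.
#' @export
render_movie <- function(trace, roi_mask = NULL, grid = c(80, 80),
                         background = 0, pixel_noise_sd = 0, seed = 1) {
  trace <- as_trace(trace)
  if (is.null(roi_mask)) {
    roi_mask <- matrix(FALSE, grid[1], grid[2])
    ctr <- round(grid / 2)
    roi_mask[(ctr[1] - 5):(ctr[1] + 5), (ctr[2] - 5):(ctr[2] + 5)] <- TRUE
  }
  if (!is.matrix(roi_mask) || !any(roi_mask)) {
    stop("`roi_mask` must be a nonempty logical matrix", call. = FALSE)
  }
  n_frames <- nrow(trace)
  bg <- rep_len(background, n_frames)
  stack <- array(0, dim = c(n_frames, nrow(roi_mask), ncol(roi_mask)))
  noise <- if (pixel_noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(stack), 0, pixel_noise_sd))
  } else {
    0
  }
  for (f in seq_len(n_frames)) {
    frame <- matrix(bg[f], nrow(roi_mask), ncol(roi_mask))
    frame[roi_mask] <- trace$value[f]
    stack[f, , ] <- frame
  }
  stack <- stack + noise
  attr(stack, "time_s") <- trace$time_s
  stack
}

#' Write / read a movie stack as multi-frame grayscale TIFF
#'
#' Values are linearly mapped to `[0, 1]` for storage (32-bit float samples);
#' the original range is restored on read from the `range` argument or, when
#' writing, returned invisibly alongside the path.
#'
#' @param stack A `frames x rows x cols` array.
#' @param path Output path.
#' @return `write_movie_tiff()` invisibly returns `list(path, range)`;
#'   `read_movie_tiff()` returns the array.
#' @export
write_movie_tiff <- function(stack, path) {
  rng <- range(stack)
  span <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(seq_len(dim(stack)[1]), function(f) {
    (stack[f, , ] - rng[1]) / span
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(list(path = path, range = rng))
}

#' @rdname write_movie_tiff
#' @param range Numeric length-2 original value range used when writing.
#' @export
read_movie_tiff <- function(path, range = c(0, 1)) {
  frames <- tiff::readTIFF(path, all = TRUE)
  span <- if (diff(range) > 0) diff(range) else 1
  stack <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) {
    stack[f, , ] <- frames[[f]] * span + range[1]
  }
  stack
}
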