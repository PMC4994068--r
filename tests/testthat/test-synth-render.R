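test_that("extracellular render places templates at spike times", {
  # no spikes, no noise: silence
  empty <- tibble::tibble(unit = character(0), time_s = numeric(0),
                          amplitude = numeric(0))
  tr <- render_extracellular(empty, total_s = 0.5, noise_sd = 0)
  expect_true(all(tr$value == 0))
  # single spike: waveform extremum within 1 ms of the spike time
  one <- tibble::tibble(unit = "A", time_s = 0.25, amplitude = 1.5)
  tr1 <- render_extracellular(one, total_s = 0.5, noise_sd = 0)
  t_ext <- tr1$time_s[which.max(abs(tr1$value))]
  expect_lt(abs(t_ext - 0.25), 0.001)
  expect_equal(max(abs(tr1$value)), 1.5, tolerance = 1e-9)
  # spike beyond the span is rejected
  bad <- tibble::tibble(unit = "A", time_s = 1.0, amplitude = 1)
  expect_error(render_extracellular(bad, total_s = 0.5), "span")
})

test_that("voltage-indicator render reduces to the bleach baseline at zero drive", {
  bm <- bleach_model(30, 15, 4, 60, 100)
  zero <- new_trace(rep(0, 1001), sample_rate = 125)
  fl <- render_arclight(zero, bm, noise_sd = 0)
  expect_equal(fl$value, bleach_baseline(bm, fl$time_s), tolerance = 1e-12)
  # and the bleach fit recovers the generating taus within 1%
  long <- new_trace(rep(0, 125 * 60 + 1), sample_rate = 125)
  fit <- fit_bleach(render_arclight(long, bm))
  expect_equal(fit$tau_fast_s, 4, tolerance = 0.01)
  expect_equal(fit$tau_slow_s, 60, tolerance = 0.01)
})

test_that("finite saturation compresses the during/post response ratio", {
  fx <- fixture_sustained(total_s = 10)
  bm <- bleach_model(30, 15, 4, 60, 100)
  ratio <- function(sat_level) {
    fl <- render_arclight(fx$rate, bm, scale = -0.05, sat_level = sat_level,
                          drive_ref = 100)
    d <- dff(detrend(fl, bm), c(0, 1.7))
    d$value <- -d$value
    in_pulse <- d$time_s >= 2 & d$time_s <= 3
    max(d$value[in_pulse]) / trace_value_at(d, 4.5)
  }
  expect_lt(ratio(0.3), ratio(Inf))
})

test_that("calcium render is sustained and linear in rate", {
  bm <- bleach_model(30, 15, 4, 60, 100)
  # zero rate: pure baseline
  zero <- new_trace(rep(0, 401), sample_rate = 125)
  g0 <- render_gcamp(zero, bm)
  expect_equal(g0$value, bleach_baseline(bm, g0$time_s), tolerance = 1e-12)
  # slow calcium decay keeps the postpulse dF/F above half its maximum
  p <- osn_params(r_spont = 0, inhib_depth = 0)
  pid <- make_odor_pulse(odor_pulse_spec(onset_s = 2, duration_s = 1, peak = 1), 10, 125)
  rate <- osn_rate(pid, p)
  g <- render_gcamp(rate, bm, ca_decay_s = 3, drive_ref = 100)
  d <- dff(detrend(g, bm), c(0, 1.7))
  expect_gt(trace_value_at(d, 4.5), 0.5 * max(d$value))
  # halving the rate halves dF/F in the linear regime
  rate_half <- rate
  rate_half$value <- rate$value / 2
  g_half <- render_gcamp(rate_half, bm, ca_decay_s = 3, drive_ref = 100)
  d_half <- dff(detrend(g_half, bm), c(0, 1.7))
  expect_equal(max(d_half$value), max(d$value) / 2, tolerance = 0.01)
  expect_error(render_gcamp(rate, bm, ca_rise_s = 1, ca_decay_s = 0.5), "exceed")
})

test_that("movie render carries the trace in the ROI and is seed-deterministic", {
  fl <- new_trace(100 + sin(seq(0, 2 * pi, length.out = 50)), 125)
  mask <- matrix(FALSE, 20, 20)
  mask[8:12, 8:12] <- TRUE
  clean <- render_movie(fl, mask, background = 5, pixel_noise_sd = 0)
  expect_equal(as.numeric(clean[3, 9, 9]), fl$value[3])
  expect_equal(as.numeric(clean[3, 1, 1]), 5)
  noisy1 <- render_movie(fl, mask, pixel_noise_sd = 0.5, seed = 7)
  noisy2 <- render_movie(fl, mask, pixel_noise_sd = 0.5, seed = 7)
  expect_identical(noisy1, noisy2)
  expect_error(render_movie(fl, matrix(FALSE, 5, 5)), "nonempty")
})

test_that("ROI averaging recovers the trace within the noise budget", {
  fl <- new_trace(100 + 3 * sin(seq(0, 4 * pi, length.out = 80)), 125)
  mask <- matrix(FALSE, 30, 30)
  mask[10:19, 10:19] <- TRUE  # 100 pixels
  sd_pix <- 2
  stack <- render_movie(fl, mask, pixel_noise_sd = sd_pix, seed = 3)
  rec <- roi_average(stack, mask)
  expect_true(all(abs(rec$value - fl$value) < 3 * sd_pix / sqrt(sum(mask))))
})

test_that("movie TIFF round-trip preserves values", {
  fl <- new_trace(100 + sin(1:30), 125)
  mask <- matrix(c(TRUE, FALSE), 10, 10)
  stack <- render_movie(fl, mask, background = 50, pixel_noise_sd = 0.1, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  info <- write_movie_tiff(stack, path)
  back <- read_movie_tiff(path, range = info$range)
  expect_equal(back, unclass(stack), ignore_attr = TRUE, tolerance = 1e-6)
})
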