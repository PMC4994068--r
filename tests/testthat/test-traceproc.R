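test_that("ROI average equals the per-frame mean over masked pixels", {
  stack <- array(0, dim = c(4, 6, 6))
  set.seed(2)
  stack[] <- rnorm(length(stack))
  mask <- matrix(FALSE, 6, 6)
  mask[2:4, 3:5] <- TRUE
  tr <- roi_average(stack, mask, sample_rate = 10)
  oracle <- vapply(1:4, function(f) mean(stack[f, , ][mask]), numeric(1))
  expect_equal(tr$value, oracle, tolerance = 1e-15)
  # uniform frames and single-pixel masks are exact
  ustack <- array(7, dim = c(3, 6, 6))
  expect_equal(roi_average(ustack, mask)$value, rep(7, 3))
  one <- matrix(FALSE, 6, 6)
  one[5, 2] <- TRUE
  expect_equal(roi_average(stack, one)$value, stack[, 5, 2])
  expect_error(roi_average(stack, matrix(FALSE, 6, 6)), "at least one")
  expect_error(roi_average(stack, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("bleach fit recovers noiseless double-exponential parameters", {
  bm <- bleach_model(30, 15, 3, 50, 100)
  tr <- new_trace(bleach_baseline(bm, seq(0, 60, by = 1 / 125)), 125)
  fit <- fit_bleach(tr)
  expect_equal(fit$a_fast, 30, tolerance = 0.01)
  expect_equal(fit$a_slow, 15, tolerance = 0.01)
  expect_equal(fit$tau_fast_s, 3, tolerance = 0.01)
  expect_equal(fit$tau_slow_s, 50, tolerance = 0.01)
  expect_equal(fit$offset, 100, tolerance = 0.01)
  expect_lt(fit$tau_fast_s, fit$tau_slow_s)
  td <- tidy(fit)
  expect_equal(td$term[3], "tau_fast_s")
  expect_lt(glance(fit)$rmse, 1e-6)
})

test_that("bleach fit handles degenerate inputs", {
  flat <- fit_bleach(new_trace(rep(5, 100), 10))
  expect_equal(flat$a_fast, 0)
  expect_equal(flat$a_slow, 0)
  expect_equal(flat$offset, 5)
  # single-exponential input: residual vanishes, baseline reproduced
  t <- seq(0, 60, by = 0.1)
  single <- new_trace(20 * exp(-t / 10) + 50, 10)
  fit <- fit_bleach(single)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(bleach_baseline(fit, t), single$value, tolerance = 1e-5)
  expect_error(fit_bleach(new_trace(1:5, 1)), "at least 10")
})

test_that("detrending a pure baseline flattens it in both modes", {
  bm <- bleach_model(30, 15, 4, 60, 100)
  t <- seq(0, 40, by = 1 / 125)
  base <- new_trace(bleach_baseline(bm, t), 125)
  expect_equal(detrend(base, bm, "divide")$value, rep(1, length(t)))
  expect_equal(detrend(base, bm, "subtract")$value, rep(100, length(t)))
  neg <- bleach_model(1, 1, 1, 10, -5)
  expect_error(detrend(base, neg, "divide"), "positive")
  # fitted-then-detrended pure baseline is flat to numerical precision
  d <- detrend(base, fit_bleach(base))
  expect_lt(stats::sd(d$value), 1e-6)
})

test_that("box-car smoothing preserves constants and composes as a kernel power", {
  const <- new_trace(rep(2.5, 40), 10)
  expect_equal(boxcar(const, width = 3, rounds = 8)$value, rep(2.5, 40))
  wiggly <- new_trace(sin(1:60) + 0.2 * cos(7 * (1:60)), 10)
  expect_equal(boxcar(wiggly, width = 1, rounds = 5)$value, wiggly$value)
  expect_error(boxcar(wiggly, width = 4), "odd")
  # 8 rounds of width 3 = one convolution with the 8-fold self-convolved kernel
  k <- rep(1 / 3, 3)
  k8 <- Reduce(function(a, b) convolve(a, rev(b), type = "open"), rep(list(k), 8))
  sm <- boxcar(wiggly, width = 3, rounds = 8)$value
  half <- (length(k8) - 1) / 2  # 8 samples each side
  interior <- (half + 1):(60 - half)
  oracle <- vapply(interior, function(i) {
    sum(wiggly$value[(i - half):(i + half)] * k8)
  }, numeric(1))
  expect_equal(sm[interior], oracle, tolerance = 1e-12)
})

test_that("percent dF/F follows the direct formula", {
  f0 <- 80
  tr <- new_trace(c(rep(f0, 20), seq(f0, 2 * f0, length.out = 20)), 10)
  d <- dff(tr, baseline_window = c(0, 1.9))
  expect_equal(d$value[1:20], rep(0, 20))
  expect_equal(d$value[40], 100)
  expect_equal(d$value, 100 * (tr$value - f0) / f0, tolerance = 1e-12)
  expect_error(dff(new_trace(rep(-1, 30), 10), c(0, 1)), "positive")
  expect_error(dff(tr, c(100, 101)), "no samples")
})

test_that("the full preprocessing chain recovers the injected response", {
  # noiseless movie -> ROI average -> bleach fit -> detrend -> box-car -> dF/F
  spec <- odor_pulse_spec(onset_s = 2, duration_s = 1, peak = 1)
  pid <- make_odor_pulse(spec, 20, 125)
  p <- osn_params()
  rate <- osn_rate(pid, p)
  bm <- bleach_model(30, 15, 4, 60, 100)
  fl <- render_arclight(rate, bm, scale = -0.05, drive_ref = 100)
  mask <- matrix(FALSE, 20, 20)
  mask[5:15, 5:15] <- TRUE
  stack <- render_movie(fl, mask, background = 10, pixel_noise_sd = 0)
  tr <- roi_average(stack, mask)
  expect_equal(tr$value, fl$value, tolerance = 1e-12)
  proc <- process_trace(tr, baseline_window = c(0, 1.7),
                        exclude_window = c(1.8, 13), invert = TRUE)
  # closed form: dF/F relative to the spontaneous-rate fluorescence level
  d0 <- p$r_spont / 100
  expected <- 100 * 0.05 * (rate$value / 100 - d0) / (1 - 0.05 * d0)
  in_pulse <- proc$time_s >= 2 & proc$time_s <= 3
  expect_equal(max(proc$value[in_pulse]), max(expected[in_pulse]),
               tolerance = 0.02)
})
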