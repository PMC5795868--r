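test_that("DC is rejected by the bandpass", {
  rec <- semg_record(matrix(3, 2000, 1), 1000)
  out <- bandpass(rec)
  expect_lt(max(abs(out$samples[500:1500, 1])), 0.01)
})

test_that("bandpass passes 100 Hz and attenuates 1 Hz as designed", {
  fs <- 1000
  spec1 <- filter_spec("bandpass", 5, 450, order = 4, zero_phase = FALSE)
  # analytic single-pass response
  g100 <- frequency_response(spec1, fs, 100)
  expect_lt(abs(g100), 1)
  g1 <- frequency_response(spec1, fs, 1)
  expect_lte(g1, -10)
  # empirical, causal mode
  rec <- sine_record(100, 1, fs = fs, dur = 4)
  amp <- steady_amplitude(bandpass(rec, spec1)$samples[, 1], fs, trim_s = 1)
  expect_lt(abs(20 * log10(amp / 1)), 1)
  rec1 <- sine_record(1, 1, fs = fs, dur = 8)
  amp1 <- steady_amplitude(bandpass(rec1, spec1)$samples[, 1], fs,
                           trim_s = 2)
  expect_lte(20 * log10(amp1 / 1), -10)
  # zero-phase (two-pass) response at least as selective
  spec2 <- filter_spec("bandpass", 5, 450, order = 4, zero_phase = TRUE)
  expect_lt(abs(frequency_response(spec2, fs, 100)), 1)
  expect_lte(frequency_response(spec2, fs, 1), -20)
})

test_that("notch kills its center and spares 2x center", {
  fs <- 1000
  spec <- filter_spec("notch", center_hz = 60, quality_factor = 30,
                      zero_phase = FALSE)
  expect_lte(frequency_response(spec, fs, 60), -30)
  expect_lt(abs(frequency_response(spec, fs, 120)), 1)
  rec60 <- sine_record(60, 1, fs = fs, dur = 30)
  amp60 <- steady_amplitude(notch(rec60, spec)$samples[, 1], fs, trim_s = 12)
  expect_lte(20 * log10(amp60 / 1), -30)
  rec120 <- sine_record(120, 1, fs = fs, dur = 6)
  amp120 <- steady_amplitude(notch(rec120, spec)$samples[, 1], fs,
                             trim_s = 2)
  expect_lt(abs(20 * log10(amp120 / 1)), 1)
  # linearity: zero in, zero out
  z <- notch(semg_record(matrix(0, 1000, 2), fs))
  expect_true(all(z$samples == 0))
})

test_that("frequency_response honors passband bounds and rejects bad freqs", {
  spec <- filter_spec("bandpass", 5, 450)
  mid <- sqrt(5 * 450)
  expect_lt(abs(frequency_response(spec, 1000, mid)), 0.5)
  g <- frequency_response(spec, 1000, c(50, 100, 200))
  expect_true(all(is.finite(g)) && all(g <= 0.1))
  expect_error(frequency_response(spec, 1000, 500), "Nyquist|fs/2")
  expect_error(bandpass(sine_record(10, 1), high_hz = 600), "Nyquist")
  expect_error(notch(sine_record(10, 1), center_hz = 700), "Nyquist")
})

test_that("filtering is linear and channel-independent", {
  set.seed(11)
  x <- matrix(rnorm(3000), 1000, 3)
  rec <- function(m) semg_record(m, 1000)
  fx <- bandpass(rec(x))$samples
  # channel independence
  for (c in 1:3)
    expect_equal(bandpass(rec(x[, c, drop = FALSE]))$samples[, 1], fx[, c])
  # linearity
  lhs <- bandpass(rec(2 * x[, 1, drop = FALSE] -
                        3 * x[, 2, drop = FALSE]))$samples[, 1]
  expect_equal(lhs, 2 * fx[, 1] - 3 * fx[, 2], tolerance = 1e-9)
})

test_that("zero-phase mode introduces no group delay", {
  fs <- 1000
  rec <- sine_record(50, 1, fs = fs, dur = 2)
  out <- bandpass(rec, zero_phase = TRUE)$samples[, 1]
  cc <- stats::ccf(out[500:1500], rec$samples[500:1500, 1],
                   lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short records are reported rather than silently padded", {
  rec <- semg_record(matrix(1, 10, 1), 1000)
  expect_error(bandpass(rec), "warm-up")
})
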