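test_that("RMS of a constant signal is exact", {
  rec <- semg_record(matrix(3, 1000, 2), 1000)
  f <- sliding_rms(rec)
  expect_true(all(f$values == 3))
})

test_that("RMS of the 100 Hz / 1 mV verification sine is A/sqrt(2)", {
  rec <- sine_record(100, 1000, fs = 1000, dur = 2)  # 1 mV = 1000 uV
  f <- sliding_rms(rec, window_ms = 200, step_ms = 5)
  expect_equal(f$values[, 1], rep(1000 / sqrt(2), nrow(f$values)),
               tolerance = 1e-3)
})

test_that("window count follows floor((n - W)/S) + 1", {
  rec <- semg_record(matrix(1, 1000, 1), 1000)
  expect_equal(nrow(sliding_rms(rec, 200, 5)$values), 161L)
  set.seed(99)
  for (i in 1:50) {
    fs <- 1000
    n <- sample(300:3000, 1)
    W <- sample(5:60, 1) * 5     # whole samples at 1 kHz
    S <- sample(1:20, 1) * 5
    if (n < W) next
    f <- sliding_rms(semg_record(matrix(rnorm(n), ncol = 1), fs),
                     window_ms = W, step_ms = S)
    expect_identical(nrow(f$values), as.integer((n - W) %/% S + 1))
    expect_true(all(diff(f$times) > 0))
  }
})

test_that("short records and non-integral windows are explicit errors", {
  rec <- semg_record(matrix(1, 100, 1), 1000)
  expect_error(sliding_rms(rec, 200, 5), "shorter than one window")
  expect_error(sliding_rms(semg_record(matrix(1, 1000, 1), 1000),
                           window_ms = 200.3), "whole number")
})

test_that("RMS is scale-equivariant and bounded by the window peak", {
  set.seed(21)
  x <- matrix(rnorm(2000), ncol = 2)
  rec <- semg_record(x, 1000)
  f1 <- sliding_rms(rec, 100, 25)
  f3 <- sliding_rms(semg_record(3 * x, 1000), 100, 25)
  expect_equal(f3$values, 3 * f1$values, tolerance = 1e-12)
  expect_true(all(f1$values <= max(abs(x)) + 1e-12))
  # window labels take the modal sample label
  lab <- rep(c("a", "b"), c(700, 300))
  fl <- sliding_rms(semg_record(x, 1000, labels = lab), 100, 25)
  expect_identical(as.character(fl$labels[1]), "a")
  expect_identical(as.character(fl$labels[length(fl$labels)]), "b")
})

test_that("streaming RMS matches the batch computation", {
  set.seed(31)
  x <- matrix(rnorm(3200), ncol = 2)
  rec <- semg_record(x, 1000)
  batch <- sliding_rms(rec, 200, 5)
  st <- rms_streamer(1000, 2, 200, 5)
  # feed in ragged chunks
  splits <- c(0, sort(sample(1:1599, 7)), 1600)
  for (i in seq_len(length(splits) - 1))
    st$feed(x[(splits[i] + 1):splits[i + 1], , drop = FALSE])
  out <- st$finalize()
  expect_equal(out$values, batch$values, tolerance = 1e-9)
  expect_equal(out$times, batch$times, tolerance = 1e-12)
})

test_that("a stream shorter than one window emits zero windows", {
  st <- rms_streamer(1000, 1, 200, 5)
  st$feed(matrix(rnorm(100), ncol = 1))
  out <- st$finalize()
  expect_identical(nrow(out$values), 0L)
})

test_that("two concatenated streams equal one stream of the concatenation", {
  set.seed(41)
  a <- matrix(rnorm(700), ncol = 1)
  b <- matrix(rnorm(900), ncol = 1)
  one <- rms_streamer(1000, 1, 50, 10)
  one$feed(rbind(a, b))
  two <- rms_streamer(1000, 1, 50, 10)
  two$feed(a); two$feed(b)
  expect_equal(two$finalize()$values, one$finalize()$values,
               tolerance = 1e-12)
})

test_that("moving average smooths as hand-computed", {
  mk <- function(v) semg_features(matrix(v, ncol = 1), 200, 5,
                                  seq_along(v), "ch01")
  f <- mk(c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  # span 1 is the identity
  expect_equal(moving_average(f, 1)$values, f$values)
  # constants are unchanged
  expect_true(all(moving_average(mk(rep(2, 9)), 5)$values == 2))
  # impulse spreads to five values of 1/5 (edges shrink)
  sm <- moving_average(f, 5)$values[, 1]
  expect_equal(sm, c(0, 0, 1/5, 1/5, 1/5, 1/5, 1/5, 0, 0))
  expect_error(moving_average(f, 11), "exceeds")
  expect_error(moving_average(f, 4), "odd")
})

test_that("total activation sums channels per window", {
  f <- semg_features(matrix(1, 5, 16), 200, 5, 1:5,
                     sprintf("ch%02d", 1:16))
  expect_equal(total_activation(f), rep(16, 5))
  v <- matrix(0, 4, 3); v[, 2] <- c(1, 2, 3, 4)
  f2 <- semg_features(v, 200, 5, 1:4, c("a", "b", "c"))
  expect_equal(total_activation(f2), c(1, 2, 3, 4))
})

test_that("flexion raises total activation above rest", {
  cfg <- two_motion_config(seed = 8, dur = 2)
  f <- sliding_rms(generate_session(cfg))
  act <- total_activation(f)
  on <- f$labels != "rest"
  expect_gt(min(act[on & steady_mask(f$labels, f$times)]),
            max(act[!on & steady_mask(f$labels, f$times)]))
})
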