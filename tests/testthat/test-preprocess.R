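# Preprocessing chain: resampling, filtering, RMS, onset, window, binarize.

test_that("block averaging takes per-second means and drops partial blocks", {
  raw <- tibble::tibble(ax = rep(2, 64), ay = rep(2, 64), az = rep(2, 64))
  out <- block_average_resample(raw)
  expect_equal(out$ax, c(2, 2))
  raw2 <- tibble::tibble(ax = 0:31, ay = rep(0, 32), az = rep(1, 32))
  expect_equal(block_average_resample(raw2)$ax, 15.5)
  raw3 <- tibble::tibble(ax = rnorm(42), ay = rnorm(42), az = rnorm(42))
  expect_equal(nrow(block_average_resample(raw3)), 1)
  expect_error(block_average_resample(raw3[1:10, ]), "shorter")
})

test_that("high-pass removes DC, passes fast oscillations, blocks slow drifts", {
  t <- 1:4000
  s3 <- tibble::tibble(ax = rep(1, 4000),
                       ay = sin(2 * pi * 0.1 * t),
                       az = sin(2 * pi * 0.0005 * t))
  hp <- highpass(s3)
  expect_lt(max(abs(hp$ax)), 1e-6)
  in_amp <- max(abs(s3$ay[1000:3000]))
  expect_lt(abs(max(abs(hp$ay[1000:3000])) / in_amp - 1), 0.01)
  expect_lt(max(abs(hp$az[1000:3000])), 0.5 * max(abs(s3$az)))
})

test_that("rms combines axes symmetrically", {
  s3 <- tibble::tibble(ax = c(1, 3, 0), ay = c(1, 4, 0), az = c(1, 0, 0))
  out <- rms_combine(s3)
  expect_equal(out$value, c(1, sqrt(25 / 3), 0))
  perm <- rms_combine(tibble::tibble(ax = s3$az, ay = s3$ax, az = s3$ay))
  expect_equal(out$value, perm$value)
  expect_error(rms_combine(list(ax = 1:3, ay = 1:2, az = 1:3)), "unequal")
})

test_that("sleep onset anchors at the start of the first quiet run", {
  expect_equal(detect_sleep_onset(rep(0.05, 700)), 1)
  x <- c(rep(0.5, 600), rep(0.05, 700))
  expect_equal(detect_sleep_onset(x), 601)
  expect_error(detect_sleep_onset(rep(0.5, 2000)), "not detected")
})

test_that("window extraction slices exactly and checks bounds", {
  x <- seq_len(28900)
  expect_identical(extract_window(x[1:28800], 1), x[1:28800])
  expect_identical(extract_window(x, 101), x[101:28900])
  expect_error(extract_window(x[1:28800], 101), "too short")
})

test_that("median binarization uses a strict threshold with ties to zero", {
  b <- binarize_median(c(1, 2, 3, 4))
  expect_equal(b$values, c(0L, 0L, 1L, 1L))
  expect_equal(b$threshold, 2.5)
  expect_equal(binarize_median(c(0, 0, 0, 5))$values, c(0L, 0L, 0L, 1L))
  expect_warning(b3 <- binarize_median(c(2, 2, 2)), "degenerate")
  expect_equal(b3$values, c(0L, 0L, 0L))
  # at most half can exceed the median; exactly half for distinct even-N input
  x <- sample(100)
  expect_equal(mean(binarize_median(x)$values), 0.5)
})

test_that("moving average is trailing valid-mode", {
  expect_equal(moving_average(c(0, 1, 2, 3), 2), c(0.5, 1.5, 2.5))
  x <- rnorm(10)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(x, 10), mean(x))
  expect_error(moving_average(x, 11), "exceeds")
})

test_that("full chain yields a 28,800-sample window from an 8.5-h night", {
  cfg <- generator_config(series_length = 30600, seed = 31,
                          magnitude_log_mean = log(0.02),
                          magnitude_log_sd = 0.3)
  night <- gen_actigraphy_night(cfg, "A", seed = 12)$values
  night[1:900] <- night[1:900] + 0.5  # pre-sleep wakefulness
  raw <- upsample_to_triaxial(night)
  pp <- preprocess_recording(raw)
  expect_length(pp$values, 28800)
  expect_lt(pp$onset_index, 1800)  # onset found within the first 30 min
})
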