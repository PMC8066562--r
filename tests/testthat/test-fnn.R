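# Delay selection, embedding and false-nearest-neighbor fractions.

test_that("autocorrelation time matches analytic cases", {
  x <- withr::with_seed(1, rnorm(10000))
  expect_equal(autocorr_time(x), 1)              # iid: rho(1) ~ 0 < 1/e
  a <- oracle_ar1(0.9, 400000, seed = 2)
  expect_equal(autocorr_time(a), 10)             # 0.9^10 < 1/e < 0.9^9
  expect_error(autocorr_time(rep(2, 100)), "constant")
})

test_that("median delay rounds the median to integer samples", {
  expect_equal(median_delay(c(3, 5, 7)), 5)
  expect_equal(median_delay(c(4, 6)), 5)
  expect_error(median_delay(numeric(0)), "non-empty")
})

test_that("delay embedding builds the right vectors", {
  e <- delay_embed(c(1, 2, 3, 4), d = 2, tau = 1)
  expect_equal(e, matrix(c(1, 2, 3, 2, 3, 4), nrow = 3))
  expect_equal(delay_embed(1:5, d = 1, tau = 3)[, 1], 1:5)
  expect_error(delay_embed(1:4, d = 3, tau = 2), "too short")
})

test_that("fnn fractions equal the brute-force all-pairs oracle", {
  h <- gen_henon(800)
  curve <- fnn_fractions(h, tau = 1, d_max = 3, pre_average = FALSE)
  for (d in 1:3) {
    ref <- oracle_fnn_dim(h, d, tau = 1)
    expect_equal(curve$fraction_test1[d], unname(ref["test1"]), tolerance = 1e-12)
    expect_equal(curve$fraction_test2[d], unname(ref["test2"]), tolerance = 1e-12)
    expect_equal(curve$fraction_combined[d], unname(ref["combined"]), tolerance = 1e-12)
  }
  x <- withr::with_seed(3, rnorm(600))
  curve2 <- fnn_fractions(x, tau = 2, d_max = 2)
  xa <- moving_average(x, 2)
  ref2 <- oracle_fnn_dim(xa, 2, tau = 2)
  expect_equal(curve2$fraction_combined[2], unname(ref2["combined"]), tolerance = 1e-12)
})

test_that("fractions live in [0,1] and are affine invariant", {
  x <- withr::with_seed(5, rnorm(1500))
  a <- fnn_fractions(x, tau = 1, d_max = 4)
  expect_true(all(a$fraction_combined >= 0 & a$fraction_combined <= 1))
  b <- fnn_fractions(5 * x + 2, tau = 1, d_max = 4)
  expect_equal(a$fraction_combined, b$fraction_combined, tolerance = 1e-12)
})

test_that("deterministic orbits converge, noise does not", {
  h <- gen_henon(4000)
  ch <- fnn_fractions(h, tau = 1, d_max = 4)
  expect_lt(max(ch$fraction_combined[ch$d >= 2]), 0.05)
  w <- withr::with_seed(8, rnorm(4000))
  cw <- fnn_fractions(w, tau = 1, d_max = 6)
  expect_gt(min(cw$fraction_combined), 0.1)
})

test_that("binarized data with identical embedded vectors is handled", {
  cfg <- generator_config(series_length = 4000, seed = 2)
  v <- gen_actigraphy_night(cfg, "A", seed = 3)$values
  bin <- as.numeric(binarize_median(v)$values)
  curve <- fnn_fractions(bin, tau = 5, d_max = 3)
  expect_true(all(is.finite(curve$fraction_combined)))
  expect_gt(sum(curve$n_zero_denom), 0)  # duplicates exist and are skipped in test 1
})
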