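# IAAFT surrogates, Welch spectra, and original-vs-surrogate comparisons.

test_that("IAAFT preserves the value distribution exactly and is seeded", {
  x <- oracle_ar1(0.8, 512, seed = 1)
  s <- iaaft(x, seed = 5)
  expect_identical(sort(as.numeric(s)), sort(x))
  expect_identical(as.numeric(iaaft(x, seed = 5)), as.numeric(s))
  expect_false(identical(as.numeric(iaaft(x, seed = 6)), as.numeric(s)))
  expect_warning(sc <- iaaft(rep(1, 64), seed = 1), "constant")
  expect_equal(as.numeric(sc), rep(1, 64))
})

test_that("IAAFT matches the periodogram of an AR(1) closely", {
  x <- oracle_ar1(0.8, 4096, seed = 2)
  s <- iaaft(x, seed = 11)
  err <- sqrt(sum((Mod(fft(as.numeric(s))) - Mod(fft(x)))^2) / sum(Mod(fft(x))^2))
  expect_lt(err, 0.05)
})

test_that("spectral error does not degrade as iterations proceed", {
  x <- oracle_ar1(0.8, 1024, seed = 3)
  amp <- Mod(fft(x))
  errs <- vapply(c(1L, 5L, 50L), function(k) {
    s <- iaaft(x, seed = 7, max_iter = k)
    sqrt(sum((Mod(fft(as.numeric(s))) - amp)^2) / sum(amp^2))
  }, numeric(1))
  expect_lte(errs[3], errs[1] + 1e-12)
})

test_that("ensembles have the requested size with pairwise distinct members", {
  x <- oracle_ar1(0.6, 256, seed = 4)
  ens <- surrogate_ensemble(x, seed = 9)
  expect_length(ens$surrogates, 20)
  keys <- vapply(ens$surrogates, function(s) paste(round(s, 10), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_length(surrogate_ensemble(x, n = 1, seed = 9)$surrogates, 1)
})

test_that("Welch PSD finds peaks and satisfies Parseval", {
  t <- seq_len(8192)
  ps <- welch_psd(sin(2 * pi * 0.1 * t))
  expect_lt(abs(ps$frequency[which.max(ps$power)] - 0.1), 1 / 2048)
  x <- gen_gaussian_noise(8192, seed = 5)
  p <- welch_psd(x)
  tot <- sum(p$power) * (p$frequency[2] - p$frequency[1])
  expect_lt(abs(tot / var(x) - 1), 0.1)
  expect_error(welch_psd(rnorm(100), segment_length = 2048), "exceeds")
})

test_that("paired original-vs-surrogate test handles regular and edge cases", {
  same <- compare_original_vs_surrogates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  sep <- compare_original_vs_surrogates(c(1, 2, 3), c(2, 3, 4))
  expect_true(is.infinite(sep$t))
  expect_equal(sep$direction, "lower")
  x <- withr::with_seed(1, rnorm(10)); y <- x + withr::with_seed(2, rnorm(10, 1))
  ours <- compare_original_vs_surrogates(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(compare_original_vs_surrogates(1:2, 1:2), "at least 3")
})

test_that("rank test needs the original to be extremal to reject at 19 surrogates", {
  expect_equal(surrogate_test(0, 1:19, "lower")$p_value, 1 / 20)
  expect_gt(surrogate_test(1.5, 1:19, "lower")$p_value, 0.05)
  expect_equal(surrogate_test(20, 1:19, "higher")$p_value, 1 / 20)
})

test_that("nonlinear regime-switching series are detected against surrogates", {
  # original binarized movement series: SampEn below every surrogate's
  detected <- vapply(1:8, function(s) {
    cfg <- generator_config(series_length = 6000, seed = s)
    v <- gen_actigraphy_night(cfg, "A", seed = 50 + s)$values
    bin <- as.numeric(binarize_median(v)$values)
    av <- moving_average(bin, 30L)
    ens <- surrogate_ensemble(av, n = 19, seed = 70 + s)
    ss <- vapply(ens$surrogates, sampen, numeric(1))
    surrogate_test(sampen(av), ss, "lower")$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.75)
})
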