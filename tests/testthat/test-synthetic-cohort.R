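# Regime-switching synthetic actigraphy generator.

test_that("generator config validates its fields", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_subjects_per_group = 0), "at least one")
  expect_error(generator_config(event_rate_high = -1), "positive")
  expect_error(generator_config(interval_cv_high = c(A = 0.3, B = 1)), "<=")
  expect_error(generator_config(state_dwell_mean = 0), "positive")
})

test_that("a generated night is non-negative, right length, and seeded", {
  cfg <- generator_config(series_length = 2000, seed = 1)
  n1 <- gen_actigraphy_night(cfg, "A", seed = 7)
  expect_length(n1$values, 2000)
  expect_true(all(n1$values >= 0))
  expect_true(all(n1$state %in% c(0L, 1L)))
  n2 <- gen_actigraphy_night(cfg, "A", seed = 7)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, gen_actigraphy_night(cfg, "A", seed = 8)$values))
  expect_error(gen_actigraphy_night(cfg, "C", seed = 1))
})

test_that("cohort has 2 x subjects x nights recordings and is reproducible", {
  cfg <- generator_config(n_subjects_per_group = 17, nights_per_subject = 3,
                          series_length = 600, seed = 21)
  coh <- gen_cohort(cfg)
  expect_equal(nrow(coh$recordings), 102)  # 34 subjects x 3 nights
  coh2 <- gen_cohort(cfg)
  expect_identical(coh$recordings$values, coh2$recordings$values)
  expect_equal(anyDuplicated(coh$recordings$seed), 0)
})

test_that("lower high-state interval CV lowers thresholded-data irregularity there", {
  # sign check over 20 seeds: the expSampEn track of the thresholded series
  # (whole-night tolerance, as the protocol measures it), averaged over the
  # high-irregularity state, is lower when intervals are regular (CV 0.3)
  diffs <- sapply(1:20, function(s) {
    cfg <- generator_config(series_length = 12000, state_dwell_min = 6000,
                            state_dwell_max = 6000, seed = s)
    na <- gen_actigraphy_night(cfg, "A", seed = 100 + s)
    nb <- gen_actigraphy_night(cfg, "B", seed = 100 + s)
    hi_en <- function(n) {
      bin <- as.numeric(binarize_median(n$values)$values)
      tv <- tidy(exp_sampen(moving_average(bin, 30L)))
      mean(tv$value[n$state[tv$t] == 1L])
    }
    hi_en(na) - hi_en(nb)
  })
  expect_gt(mean(diffs > 0, na.rm = TRUE), 0.75)
})

test_that("null configuration makes the group label irrelevant", {
  cfg <- generator_config(interval_cv_high = c(A = 0.7, B = 0.7),
                          series_length = 3000, seed = 3)
  a <- gen_actigraphy_night(cfg, "A", seed = 42)
  b <- gen_actigraphy_night(cfg, "B", seed = 42)
  expect_identical(a$values, b$values)  # same seed, same parameters
})

test_that("subject traits are seeded multipliers shared across nights", {
  cfg <- generator_config(seed = 5)
  tr1 <- subject_traits(cfg, seed = 99)
  tr2 <- subject_traits(cfg, seed = 99)
  expect_identical(tr1, tr2)
  expect_true(all(unlist(tr1) > 0))
})

test_that("triaxial upsampler round-trips through the preprocessing chain", {
  cfg <- generator_config(series_length = 1200, seed = 8,
                          magnitude_log_mean = log(0.02),
                          magnitude_log_sd = 0.3)
  v <- gen_actigraphy_night(cfg, "A", seed = 2)$values
  raw <- upsample_to_triaxial(v)
  s1 <- block_average_resample(raw)
  mag <- rms_combine(highpass(s1))
  expect_length(mag$value, 1200)
  # high-pass removes the 1 G gravity offset; spikes survive approximately
  expect_lt(abs(median(mag$value) - 0), 0.01)
  expect_gt(cor(mag$value, v), 0.95)
})
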