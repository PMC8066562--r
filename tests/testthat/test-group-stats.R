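# Cohort-level statistics: smoothing, pointwise tracks, representatives,
# Spearman tables.

test_that("60-min smoothing is the trailing moving-average primitive", {
  x <- rep(2, 4000)
  expect_equal(smooth_60min(x), rep(2, 401))
  imp <- c(rep(0, 3599), 1, rep(0, 3600))
  sm <- smooth_60min(imp)
  expect_equal(max(sm), 1 / 3600)
  expect_equal(sum(sm > 0), 3600)
  expect_length(smooth_60min(rep(1, 3600)), 1)
  expect_error(smooth_60min(rep(1, 100)), "shorter")
})

test_that("pointwise t-test track is null for identical groups", {
  base <- withr::with_seed(1, matrix(rnorm(5 * 50), nrow = 5))
  long <- do.call(rbind, lapply(1:5, function(s) {
    data.frame(subject = s, time = 1:50, value = base[s, ])
  }))
  df <- rbind(cbind(long, group = "A"),
              cbind(transform(long, subject = subject + 10), group = "B"))
  tr <- pointwise_group_ttest(df)
  expect_true(all(abs(tr$t_stat) < 1e-12))
  expect_true(all(!tr$significant_lower_B))
  expect_equal(nrow(tr), 50)
})

test_that("pointwise track flags times where group B sits lower", {
  withr::with_seed(2, {
    mkgrp <- function(g, shift) do.call(rbind, lapply(1:8, function(s) {
      data.frame(group = g, subject = s, time = 1:40,
                 value = rnorm(40, mean = ifelse(1:40 > 20, shift, 0), sd = 0.5))
    }))
    df <- rbind(mkgrp("A", 0), mkgrp("B", -2))
  })
  tr <- pointwise_group_ttest(df)
  expect_true(all(tr$significant_lower_B[tr$time > 20]))
  expect_error(pointwise_group_ttest(df[df$group == "A", ]), "two groups")
})

test_that("representative percentiles use linear interpolation", {
  r <- representative_values(as.numeric(1:100))
  expect_equal(r$p_high, 90.1)
  expect_equal(r$p_low, 10.9)
  rc <- representative_values(rep(3.3, 10))
  expect_equal(rc$p_high, rc$p_low)
  x <- withr::with_seed(3, rexp(57))
  rr <- representative_values(x)
  expect_gte(rr$p_high, rr$p_low)
})

test_that("representative t-test follows the one-tailed Student convention", {
  null <- representative_ttest(c(2, 3, 4), c(2, 3, 4))
  expect_equal(null$t, 0)
  expect_equal(null$p_value, 0.5)
  # T = 2.17 at 17 + 17 - 2 = 32 df must give one-tailed p ~ 0.019
  base <- withr::with_seed(4, rnorm(17))
  base <- (base - mean(base)) / sd(base)           # mean 0, var 1 exactly
  delta <- 2.17 * sqrt(2 / 17)
  res <- representative_ttest(base + delta, base)
  expect_equal(res$t, 2.17, tolerance = 1e-10)
  expect_lt(abs(res$p_value - 0.019), 5e-4)
  # scale invariance
  res2 <- representative_ttest(2 * (base + delta), 2 * base)
  expect_equal(res2$t, res$t, tolerance = 1e-10)
  expect_error(representative_ttest(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("spearman pairs are monotone-invariant and handle constants", {
  t <- 1:2000
  x <- withr::with_seed(5, cumsum(rnorm(2000)))
  ser <- list(a = tibble::tibble(t = t, value = x),
              b = tibble::tibble(t = t, value = exp(x / 10)),
              d = tibble::tibble(t = t, value = -x^3),
              const = tibble::tibble(t = t, value = rep(1, 2000)))
  sp <- spearman_pairs(ser, pairs = rbind(c("a", "a"), c("a", "b"),
                                          c("a", "d"), c("a", "const")),
                       smoothing = 1L)
  expect_equal(sp$rho[1], 1)
  expect_equal(sp$rho[2], 1)
  expect_equal(sp$rho[3], -1)
  expect_true(is.na(sp$rho[4]))
})

test_that("independent noise decorrelates before smoothing", {
  rhos <- vapply(1:5, function(s) {
    a <- withr::with_seed(s, rnorm(25000))
    b <- withr::with_seed(1000 + s, rnorm(25000))
    ser <- list(a = tibble::tibble(t = 1:25000, value = a),
                b = tibble::tibble(t = 1:25000, value = b))
    spearman_pairs(ser, smoothing = 1L)$rho
  }, numeric(1))
  expect_true(all(abs(rhos) < 0.05))
})

test_that("spearman table aggregates per pair and scale", {
  per <- tibble::tibble(recording = rep(c("r1", "r2"), each = 2),
                        scale = rep(c(30, 100), 2),
                        pair = rep(c("x-y", "x-y"), 2),
                        rho = c(0.5, 0.7, 0.9, 0.3))
  tab <- spearman_table(per)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rho_mean[tab$scale == 30], 0.7)
  expect_equal(tab$n_recordings, c(2L, 2L))
})
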