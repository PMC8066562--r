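# ApEn / SampEn / expSampEn and the multiscale moving-average protocol.

test_that("all three measures equal the brute-force oracle on random series", {
  for (i in 1:6) {
    x <- switch(1 + i %% 3,
                withr::with_seed(i, rnorm(50)),
                withr::with_seed(i, cumsum(rnorm(120))),
                withr::with_seed(i, round(runif(150), 1)))
    m <- if (i %% 2 == 0) 2L else 3L
    ref <- oracle_entropy(x, m = m, r = 0.2)
    expect_equal(apen(x, m = m), ref$apen, tolerance = 1e-12)
    expect_equal(sampen(x, m = m), ref$sampen, tolerance = 1e-12)
    expect_equal(exp_sampen(x, m = m)$values, ref$exps, tolerance = 1e-12)
  }
})

test_that("mean of expSampEn equals ApEn exactly", {
  for (i in 1:20) {
    x <- withr::with_seed(100 + i, rnorm(300))
    expect_equal(mean(exp_sampen(x)$values), apen(x), tolerance = 1e-12)
  }
})

test_that("saturated tolerance gives zero entropy, periodic series zero SampEn", {
  x <- 5 + withr::with_seed(1, rnorm(100)) * 1e-6
  big <- exp_sampen(x, r = 1e6)
  expect_true(all(big$values == 0))
  expect_equal(apen(x, r = 1e6), 0)
  per <- rep(c(0, 1), 200)  # period 2 = template length m
  expect_equal(sampen(per, m = 2, r = 0.2), 0)
})

test_that("entropies are invariant under positive affine transforms", {
  x <- withr::with_seed(7, rnorm(400))
  expect_equal(apen(x), apen(3 * x + 10), tolerance = 1e-12)
  expect_equal(sampen(x), sampen(3 * x + 10), tolerance = 1e-12)
  expect_equal(exp_sampen(x)$values, exp_sampen(3 * x + 10)$values,
               tolerance = 1e-12)
})

test_that("SampEn orders white noise above AR(1) above periodic", {
  wins <- vapply(1:20, function(s) {
    w <- withr::with_seed(s, runif(3000))
    a <- oracle_ar1(0.9, 3000, seed = 1000 + s)
    sampen(w) > sampen(a)
  }, logical(1))
  expect_true(all(wins))
  expect_gt(sampen(withr::with_seed(1, runif(3000))), sampen(rep(c(0, 1), 1500)))
})

test_that("degenerate entropy inputs raise the documented conditions", {
  expect_error(apen(rep(1, 50)), "tolerance")
  expect_error(sampen(c(1, 2), m = 2), "at least")
  # far-apart values: no m-template matches at all
  x <- c(0, 1e6, -1e6, 5e5, -5e5, 2e6, -2e6, 3e6, -3e6, 4e6)
  expect_error(sampen(x, m = 2, r = 1e-9), "undefined")
})

test_that("multiscale profile recomputes tolerance per scale", {
  x <- withr::with_seed(9, rnorm(800))
  prof <- multiscale_profile(x, scales = c(1L, 10L, 50L))
  expect_equal(nrow(prof), 3)
  expect_equal(prof$apen[1], apen(x), tolerance = 1e-12)
  expect_equal(prof$sampen[1], sampen(x), tolerance = 1e-12)
  # each scale's expSampEn mean reproduces its ApEn (identity holds per scale)
  for (i in 1:3) {
    expect_equal(mean(prof$exp_sampen[[i]]$values), prof$apen[i],
                 tolerance = 1e-12)
  }
  # time stamps line up with the end of the averaging + template window
  es <- prof$exp_sampen[[2]]
  expect_equal(tidy(es)$t[1], 10 + 2)  # scale 10, m = 2
})

test_that("smoothing to coarser scales lowers SampEn of persistent noise", {
  deltas <- vapply(1:6, function(s) {
    x <- gen_fgn(0.9, 6000, seed = 400 + s)
    prof <- multiscale_profile(x, scales = c(30L, 300L))
    prof$sampen[1] - prof$sampen[2]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
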