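# Reference noise processes and the Henon map.

test_that("gaussian noise is seeded, standardized and validated", {
  expect_identical(gen_gaussian_noise(4, seed = 11), gen_gaussian_noise(4, seed = 11))
  expect_false(identical(gen_gaussian_noise(4, seed = 11), gen_gaussian_noise(4, seed = 12)))
  x <- gen_gaussian_noise(1e5, seed = 3)
  expect_lt(abs(mean(x)), 3 / sqrt(1e5))
  expect_lt(abs(var(x) - 1), 0.05)
  expect_error(gen_gaussian_noise(1, seed = 1), "at least|>= 2")
})

test_that("fGn has the right marginals and H = 0.5 reduces to white noise", {
  x <- gen_fgn(0.5, 10000, seed = 5)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(10000))
  y <- gen_fgn(0.8, 20000, seed = 6)
  expect_lt(abs(var(y) - 1), 0.1)
  expect_gt(cor(y[-1], y[-length(y)]), 0.15)  # persistent process
  expect_error(gen_fgn(1.2, 1000, seed = 1), "inside")
  expect_error(gen_fgn(0, 1000, seed = 1), "inside")
  expect_identical(gen_fgn(0.7, 512, seed = 2), gen_fgn(0.7, 512, seed = 2))
})

test_that("fGn DFA exponent tracks the Hurst input", {
  a <- dfa(gen_fgn(0.8, 28800, seed = 4), dfa_scales(), c(300, 7200))$alpha
  expect_gt(a, 0.72)
  expect_lt(a, 0.88)
})

test_that("pink noise has 1/f periodogram slope and seed contract", {
  n <- 2^15
  x <- gen_pink_noise(n, seed = 9)
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  keep <- sp$freq > 1e-3 & sp$freq < 0.4
  slope <- coef(lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2]
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
  y <- gen_pink_noise(n, seed = 10)
  expect_false(identical(x, y))
  sp2 <- stats::spec.pgram(y, plot = FALSE, taper = 0)
  slope2 <- coef(lm(log10(sp2$spec[keep]) ~ log10(sp2$freq[keep])))[2]
  expect_lt(abs(slope - slope2), 0.15)
  expect_error(gen_pink_noise(8, seed = 1), ">= 16")
})

test_that("Henon map orbits are bounded, fixed points hold, divergence errors", {
  h <- gen_henon(5000)
  expect_true(all(abs(h) <= 1.5))
  expect_true(all(gen_henon(100, a = 0, b = 0) == 1))
  expect_error(gen_henon(1000, a = 6, b = 0.3, x0 = c(0.1, 0.1)), "diverged")
  expect_identical(gen_henon(500), gen_henon(500))
})
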