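# Canonical validation processes: white noise, fractional Gaussian noise,
# 1/f (pink) noise, and the Henon map.  These are the reference inputs with
# known complexity signatures used to validate the analysis chain (DFA
# alpha ~ 0.5 / H / 1.0, FNN convergence for deterministic maps, ...).

#' Seeded Gaussian white noise
#'
#' @param n Length of the series (`>= 2`).
#' @param seed Integer seed; the same `(n, seed)` always yields the same
#'   draw.
#' @return Numeric vector of `n` i.i.d. standard normal values.
#' @examples
#' gen_gaussian_noise(5, seed = 1)
#' @export
gen_gaussian_noise <- function(n, seed) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be >= 2")
  with_seed_(seed, rnorm(n))
}

#' Fractional Gaussian noise via circulant embedding
#'
#' Exact-covariance synthesis (Davies-Harte): the fGn autocovariance
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2} is embedded in
#' a circulant matrix whose eigenvalues are obtained by FFT, and a complex
#' Gaussian vector is colored accordingly.  The DFA scaling exponent of the
#' output is approximately `hurst`.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param n Length of the series.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
gen_fgn <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1) {
    abort("`hurst` must lie strictly inside (0, 1)")
  }
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be >= 2")
  if (abs(hurst - 0.5) < 1e-12) return(gen_gaussian_noise(n, seed))

  k <- 0:(n - 1)
  gamma_k <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                      abs(k - 1)^(2 * hurst))
  m <- 2L * (n - 1L)
  circ <- c(gamma_k, gamma_k[(n - 1L):2L])
  lambda <- Re(fft(circ))
  # fGn eigenvalues are nonnegative in theory; clip roundoff-scale negatives
  lambda[lambda < 0 & lambda > -1e-8 * max(lambda)] <- 0
  if (any(lambda < 0)) abort("circulant embedding failed (negative eigenvalue)")

  half <- m %/% 2L  # = n - 1
  with_seed_(seed, {
    w <- complex(length.out = m)
    w[1L] <- rnorm(1)                              # zero frequency, real
    if (half > 1L) {
      w[2L:half] <- complex(real = rnorm(half - 1L),
                            imaginary = rnorm(half - 1L)) / sqrt(2)
    }
    w[half + 1L] <- rnorm(1)                       # Nyquist, real
    if (half + 2L <= m) w[(half + 2L):m] <- Conj(w[half:2L])
    x <- Re(fft(sqrt(lambda) * w)) / sqrt(m)
    x[1:n]
  })
}

#' 1/f (pink) noise by spectral synthesis
#'
#' Builds a Gaussian series whose power spectral density is proportional to
#' `1/f`: Fourier amplitudes are set to \eqn{f^{-1/2}} with uniformly random
#' phases (conjugate-symmetric), then inverse-transformed and standardized
#' to zero mean / unit variance.
#'
#' @param n Length of the series (`>= 16`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_pink_noise <- function(n, seed) {
  n <- as.integer(n)
  if (n < 16L) abort("`n` must be >= 16")
  nf <- n %/% 2L
  with_seed_(seed, {
    f <- (1:nf) / n
    amp <- f^(-0.5)
    phase <- runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    # Nyquist bin must be real for even n
    if (n %% 2L == 0L) spec[nf] <- complex(real = amp[nf] * sign(cos(phase[nf])))
    full <- complex(length.out = n)
    full[2:(nf + 1L)] <- spec
    idx <- 2:(nf + 1L)
    tgt <- n + 2L - idx
    sel <- tgt != idx  # for even n the Nyquist bin is its own mirror
    full[tgt[sel]] <- Conj(full[idx[sel]])
    x <- Re(fft(full, inverse = TRUE)) / n
    (x - mean(x)) / sd(x)
  })
}

#' Henon map orbit
#'
#' Iterates \eqn{x_{t+1} = 1 - a x_t^2 + b x_{t-1}} and returns the
#' x-coordinate orbit after discarding a transient.  With the classical
#' parameters (a = 1.4, b = 0.3) the orbit lies on the Henon attractor, a
#' low-dimensional deterministic set; it is the canonical positive control
#' for false-nearest-neighbor convergence.
#'
#' @param n Orbit length after the transient (`>= 100`).
#' @param x0 Numeric pair of initial values \eqn{(x_0, x_1)}.
#' @param a,b Map parameters.
#' @param transient Iterations discarded before recording (`>= 100`).
#' @return Numeric vector of length `n`.
#' @export
gen_henon <- function(n, x0 = c(0, 0), a = 1.4, b = 0.3, transient = 100L) {
  n <- as.integer(n)
  if (n < 100L) abort("`n` must be >= 100")
  transient <- max(as.integer(transient), 100L)
  if (length(x0) != 2L || !is.numeric(x0)) abort("`x0` must be a numeric pair")
  total <- n + transient
  x <- numeric(total)
  xm1 <- x0[1]; xc <- x0[2]
  for (t in seq_len(total)) {
    xn <- 1 - a * xc^2 + b * xm1
    if (!is.finite(xn) || abs(xn) > 1e10) {
      abort("Henon orbit diverged (|x| > 1e10); map parameters are outside the bounded regime")
    }
    x[t] <- xn
    xm1 <- xc; xc <- xn
  }
  x[(transient + 1L):total]
}
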