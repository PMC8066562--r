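# IAAFT surrogates: constrained randomizations preserving the amplitude
# distribution exactly and the power spectrum approximately.  The null
# hypothesis they embody is a stationary linear Gaussian process observed
# through a static monotone transform; complexity measures falling outside
# the surrogate distribution indicate nonlinear structure.

#' Generate one IAAFT surrogate
#'
#' Iterative amplitude-adjusted Fourier transform: starting from a seeded
#' random shuffle, alternate (a) replacing the Fourier amplitudes with the
#' original ones while keeping the current phases, and (b) rank-remapping
#' the result onto the original sorted values.  Iteration stops when the
#' rank ordering no longer changes, or after `max_iter` rounds.  The final
#' step is the rank remap, so the surrogate's value distribution equals the
#' original's *exactly* (it is a permutation of the original values), while
#' the spectrum is matched approximately.
#'
#' @param values Numeric series of length >= 32.
#' @param seed Integer seed for the initial shuffle.
#' @param max_iter Maximum number of iterations (default 100).
#' @return Numeric vector: the surrogate series, with attribute
#'   `iterations` (rounds used).  A constant series is returned unchanged
#'   with a warning.
#' @export
iaaft <- function(values, seed, max_iter = 100L) {
  assert_numeric_series(values, min_len = 32L)
  if (pop_sd(values) == 0) {
    warn("constant series: IAAFT surrogate is the series itself")
    return(structure(values, iterations = 0L))
  }
  sorted_vals <- sort(values)
  amp <- Mod(fft(values))
  s <- with_seed_(seed, sample(values))
  prev_order <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # (a) spectrum step: impose original amplitudes, keep current phases
    sp <- fft(s)
    phase <- Arg(sp)
    s2 <- Re(fft(complex(modulus = amp, argument = phase),
                 inverse = TRUE)) / length(values)
    # (b) amplitude step: rank-remap onto the original values
    ord <- order(s2)
    s <- numeric(length(values))
    s[ord] <- sorted_vals
    if (identical(ord, prev_order) || iter >= max_iter) break
    prev_order <- ord
  }
  structure(s, iterations = iter)
}

#' Ensemble of IAAFT surrogates
#'
#' @inheritParams iaaft
#' @param n Ensemble size (default 20).
#' @return A `surrogate_ensemble` list: `surrogates` (list of numeric
#'   vectors), `iterations_used`, `seed`.
#' @export
surrogate_ensemble <- function(values, n = 20L, seed, max_iter = 100L) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1")
  surr <- lapply(seq_len(n), function(i) {
    iaaft(values, seed = derive_seed(seed, "surrogate", i),
          max_iter = max_iter)
  })
  structure(
    list(surrogates = lapply(surr, as.numeric),
         iterations_used = vapply(surr, attr, integer(1), "iterations"),
         seed = seed),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("IAAFT surrogate ensemble: %d members, %d-%d iterations\n",
              length(x$surrogates), min(x$iterations_used),
              max(x$iterations_used)))
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-windowed, mean-removed, 50%-overlapping
#' segments; one-sided density normalized so that
#' `sum(power) * df ~ var(values)` (Parseval).
#'
#' @param values Numeric series.
#' @param segment_length Segment length in samples (default 2,048).
#' @param overlap Fractional overlap between segments in `[0, 1)` (default
#'   0.5).
#' @param fs Sampling rate in Hz (default 1).
#' @return Tibble with columns `frequency` (0 to `fs/2`) and `power`.
#' @export
welch_psd <- function(values, segment_length = 2048L, overlap = 0.5, fs = 1) {
  assert_numeric_series(values)
  L <- as.integer(segment_length)
  if (L > length(values)) abort("`segment_length` exceeds series length")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(values) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  norm <- fs * sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- values[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    (Mod(fft(seg))^2 / norm)[1:(L %/% 2L + 1L)]
  }, numeric(L %/% 2L + 1L))
  pow <- rowMeans(segs)
  # one-sided: double everything except DC and Nyquist
  pow[2:(L %/% 2L)] <- 2 * pow[2:(L %/% 2L)]
  tibble::tibble(frequency = (0:(L %/% 2L)) * fs / L, power = pow)
}

#' Paired comparison of originals against surrogate means
#'
#' Student's t-test on the paired differences (original minus per-recording
#' surrogate-ensemble mean) of any complexity metric across recordings.
#'
#' @param original Numeric vector: the metric computed on each recording.
#' @param surrogate_mean Numeric vector: the mean of the metric over each
#'   recording's surrogate ensemble (same order).
#' @return Tibble with `t`, `df`, `p_value` (two-sided), `mean_difference`,
#'   `direction` (`"lower"`/`"higher"`/`"equal"`, sign of original -
#'   surrogate) and `n`.  Identical pairs give `t = 0, p = 1`; a non-zero
#'   constant difference is flagged as perfect separation (`t = Inf`,
#'   `p = 0`).
#' @export
compare_original_vs_surrogates <- function(original, surrogate_mean) {
  if (length(original) != length(surrogate_mean)) {
    abort("`original` and `surrogate_mean` must be paired (equal length)")
  }
  n <- length(original)
  if (n < 3L) abort("need at least 3 pairs")
  d <- original - surrogate_mean
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    t_stat <- if (md == 0) 0 else Inf * sign(md)
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  }
  tibble::tibble(
    t = t_stat, df = n - 1L, p_value = p, mean_difference = md,
    direction = if (md < 0) "lower" else if (md > 0) "higher" else "equal",
    n = n)
}

#' Single-recording surrogate rank test
#'
#' Rank-based nonlinearity test for one recording: the metric on the
#' original is ranked within the surrogate ensemble.  With `n` surrogates
#' and alternative `"lower"`, `p = (1 + #\{surrogate <= original\})/(n+1)`;
#' with 19 or 20 surrogates rejection at the 0.05 level requires the
#' original to be more extreme than every surrogate.
#'
#' @param original_value Metric on the original series.
#' @param surrogate_values Metric on each surrogate.
#' @param alternative `"lower"` (default), `"higher"`, or `"two.sided"`.
#' @return Tibble with `p_value`, `rank`, `n_surrogates`.
#' @export
surrogate_test <- function(original_value, surrogate_values,
                           alternative = c("lower", "higher", "two.sided")) {
  alternative <- match.arg(alternative)
  ns <- length(surrogate_values)
  if (ns < 1L) abort("need at least one surrogate value")
  p_low <- (1 + sum(surrogate_values <= original_value)) / (ns + 1)
  p_high <- (1 + sum(surrogate_values >= original_value)) / (ns + 1)
  p <- switch(alternative,
              lower = p_low, higher = p_high,
              two.sided = min(1, 2 * min(p_low, p_high)))
  tibble::tibble(p_value = p,
                 rank = sum(surrogate_values < original_value) + 1L,
                 n_surrogates = ns)
}
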