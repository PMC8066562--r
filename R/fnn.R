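# Determinism detection: autocorrelation-time delay selection, delay
# embedding, and false-nearest-neighbor fractions.  A deterministic system
# drives the FNN fraction to zero once the embedding dimension unfolds the
# attractor; for a stochastic series the fraction never reaches zero.

#' Autocorrelation time (1/e decay lag)
#'
#' The smallest positive lag `k` at which the normalized autocorrelation
#' (mean-removed, biased estimator) drops below `1/e`.  This is the common
#' delay choice for attractor reconstruction.
#'
#' @param values Numeric, non-constant series of length >= 10.
#' @return Integer lag in samples.
#' @export
autocorr_time <- function(values) {
  assert_numeric_series(values, min_len = 10L)
  if (pop_sd(values) == 0) abort("constant series: autocorrelation undefined")
  n <- length(values)
  max_lag <- n %/% 2L
  # biased mean-removed autocorrelation via FFT (Wiener-Khinchin)
  xc <- values - mean(values)
  np <- nextn(2L * n)
  sp <- fft(c(xc, rep(0, np - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE))[seq_len(max_lag + 1L)] / np
  rho <- (ac / ac[1])[-1]
  idx <- which(rho < exp(-1))
  if (length(idx) == 0L) {
    abort("autocorrelation never decays below 1/e within N/2 lags")
  }
  idx[1]
}

#' Median delay across recordings
#'
#' The embedding delay used for a cohort is the median of the per-recording
#' autocorrelation times, rounded to the nearest integer sample.
#'
#' @param lags Numeric vector of per-recording autocorrelation times.
#' @return Integer delay tau.
#' @export
median_delay <- function(lags) {
  if (length(lags) == 0L) abort("`lags` must be non-empty")
  as.integer(round(median(lags)))
}

#' Delay embedding
#'
#' Builds the delay vectors
#' \eqn{y_i = (x_i, x_{i+\tau}, \ldots, x_{i+(d-1)\tau})} for
#' \eqn{i = 1, \ldots, N - (d-1)\tau}.
#'
#' @param values Numeric series.
#' @param d Embedding dimension.
#' @param tau Delay in samples.
#' @return Numeric matrix with one row per delay vector and `d` columns.
#' @export
delay_embed <- function(values, d, tau) {
  assert_numeric_series(values)
  d <- as.integer(d); tau <- as.integer(tau)
  if (d < 1L || tau < 1L) abort("`d` and `tau` must be >= 1")
  n_vec <- length(values) - (d - 1L) * tau
  if (n_vec < 1L) abort("series too short for this (d, tau)")
  out <- vapply(seq_len(d),
                function(k) values[(1L + (k - 1L) * tau):((k - 1L) * tau + n_vec)],
                numeric(n_vec))
  matrix(out, nrow = n_vec, ncol = d)
}

#' False-nearest-neighbor fractions
#'
#' The series is first moving-averaged over the delay `tau` (denoising step
#' of the reference protocol), then for each embedding dimension
#' `d = 1..d_max` every point's nearest neighbor is found in the
#' `d`-dimensional delay embedding (Euclidean metric, excluding neighbors
#' within `theiler` samples in time; ties break to the smallest index), and
#' two falseness tests are applied:
#' \describe{
#'   \item{test 1 (ratio)}{the extension distance
#'     `|x(i + d tau) - x(nn + d tau)|` exceeds `A` times the d-dimensional
#'     neighbor distance — the neighborhood blows apart when the next
#'     coordinate is revealed;}
#'   \item{test 2 (size)}{the (d+1)-dimensional distance exceeds `B` times
#'     the series SD — the "neighbors" were never close on the scale of
#'     the data.}
#' }
#' The combined fraction counts points failing either test.  Pairs with
#' identical embedded vectors (zero denominator in test 1, frequent for
#' binarized data) are not counted as false by test 1 but remain eligible
#' for test 2; their count is reported as `n_zero_denom`.
#'
#' @param values Numeric series.
#' @param tau Delay in samples (e.g. from [median_delay()]).
#' @param d_max Maximum embedding dimension (default 10).
#' @param A Ratio-test threshold (default 10).
#' @param B Size-test threshold (default 2).
#' @param theiler Theiler exclusion window in samples; defaults to `tau`.
#' @param pre_average If `TRUE` (default) apply the moving average over
#'   `tau` before the FNN counting.
#' @return An `fnn_curve` tibble with columns `d`, `fraction_test1`,
#'   `fraction_test2`, `fraction_combined`, `n_pairs`, `n_zero_denom`, and
#'   attributes `tau`, `sigma`.
#' @export
fnn_fractions <- function(values, tau, d_max = 10L, A = 10, B = 2,
                          theiler = tau, pre_average = TRUE) {
  tau <- as.integer(tau); d_max <- as.integer(d_max)
  if (tau < 1L || d_max < 1L) abort("`tau` and `d_max` must be >= 1")
  if (A <= 0 || B <= 0) abort("thresholds `A` and `B` must be positive")
  x <- if (pre_average && tau > 1L) moving_average(values, tau) else values
  if (length(x) <= (d_max + 1L) * tau + 1L) {
    abort("series too short for d_max embedding after the tau moving average")
  }
  sigma <- pop_sd(x)
  if (sigma == 0) abort("constant series after averaging: FNN undefined")
  rows <- lapply(seq_len(d_max), function(d) {
    r <- fnn_dim(x, d, tau, A, B, as.integer(theiler), sigma)
    tibble::tibble(d = d,
                   fraction_test1 = r$fraction_test1,
                   fraction_test2 = r$fraction_test2,
                   fraction_combined = r$fraction_combined,
                   n_pairs = r$n_pairs, n_zero_denom = r$n_zero_denom)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tau") <- tau
  attr(out, "sigma") <- sigma
  class(out) <- c("fnn_curve", class(out))
  out
}

#' @export
autoplot.fnn_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object)[c("d", "fraction_test1", "fraction_test2",
                            "fraction_combined")],
    -"d", names_to = "test", values_to = "fraction")
  df$test <- sub("fraction_", "", df$test)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$fraction,
                                   colour = .data$test)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(df$d)) +
    ggplot2::labs(x = "embedding dimension d", y = "fraction of FNN") +
    ggplot2::theme_minimal()
}
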