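# Distribution-comparison stationarity screen: does the first half of the
# night look like the whole night?

#' Chi-square stationarity screen
#'
#' Bins the *entire* series into `n_bins` equal-probability (quantile) bins,
#' counts how many first-half samples fall in each bin, and compares those
#' observed counts against the expectation `(N/2) * p_bin` where `p_bin`
#' are the whole-series bin proportions, with a Pearson chi-square statistic
#' on `n_bins - 1` degrees of freedom.  Rejection (`p < level`) indicates
#' that the first half of the night is distributed differently from the
#' night as a whole, i.e. the series is non-stationary in distribution.
#'
#' Quantile bins make the statistic invariant under strictly monotone
#' transforms of the data.  When the series has no more distinct values
#' than bins (e.g. a binarized series with `n_bins = 2`), the distinct
#' values themselves are used as bins.  Note the two halves overlap (the
#' first half is part of the whole), which makes the test conservative
#' relative to its nominal chi-square reference; the screen is used as in
#' the original protocol, not as an exact test.
#'
#' @param values Numeric series.
#' @param n_bins Number of bins (5 for magnitude data, 2 for binarized
#'   data in the reference protocol).
#' @param level Significance level (default 0.05).
#' @return A `stationarity_result` list: `statistic`, `dof`, `p_value`,
#'   `rejected`, `n_bins` (the number of bins actually used).
#' @export
stationarity_chi2 <- function(values, n_bins = 5L, level = 0.05) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be >= 2")
  assert_numeric_series(values, min_len = 2L * n_bins * 5L)
  n <- length(values)
  uniq <- sort(unique(values))
  if (length(uniq) == 1L) abort("constant series: stationarity test is degenerate")

  if (length(uniq) <= n_bins) {
    breaks <- c(-Inf, uniq[-length(uniq)], Inf)
  } else {
    qs <- quantile(values, probs = seq(0, 1, length.out = n_bins + 1L),
                   names = FALSE, type = 7)
    breaks <- unique(qs)
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
    if (length(breaks) < 3L) {
      # a point mass holding most of the distribution defeats quantile
      # binning; fall back to splitting at that mass (presence/absence)
      tab <- table(values)
      mode_val <- as.numeric(names(tab)[which.max(tab)])
      breaks <- c(-Inf, mode_val, Inf)
      warn(sprintf(
        "quantile bins collapsed (point mass at %g); using a 2-bin split",
        mode_val))
    }
  }
  k <- length(breaks) - 1L

  whole <- tabulate(cut(values, breaks, labels = FALSE, right = TRUE), nbins = k)
  half_n <- n %/% 2L
  first <- tabulate(cut(values[seq_len(half_n)], breaks, labels = FALSE,
                        right = TRUE), nbins = k)
  expected <- half_n * whole / n
  if (any(expected < 1)) {
    abort("expected count < 1 in some bin: chi-square approximation unreliable")
  }
  stat <- sum((first - expected)^2 / expected)
  dof <- k - 1L
  p <- pchisq(stat, df = dof, lower.tail = FALSE)
  structure(
    list(statistic = stat, dof = dof, p_value = p,
         rejected = p < level, n_bins = k),
    class = "stationarity_result"
  )
}

#' @export
print.stationarity_result <- function(x, ...) {
  cat(sprintf(
    "Chi-square stationarity screen: X2 = %.3f (df = %d), p = %.3g -> %s\n",
    x$statistic, x$dof, x$p_value,
    if (x$rejected) "non-stationary (rejected)" else "not rejected"))
  invisible(x)
}

#' @export
tidy.stationarity_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, dof = x$dof, p_value = x$p_value,
                 rejected = x$rejected, n_bins = x$n_bins)
}
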