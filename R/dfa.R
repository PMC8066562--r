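# Detrended fluctuation analysis (DFA1): long-range temporal correlation of
# the movement series, summarized by the scaling exponent alpha of
# F(n) ~ n^alpha.  alpha ~ 0.5 for temporally uncorrelated data, ~1 for
# 1/f-scaled (long-range correlated) data.

#' Default DFA scale grid
#'
#' `n_scales` log-spaced integer window sizes between `min_scale` and
#' `max_scale` (default 300-7,200 samples, i.e. 5 min to 2 h at 1 Hz).
#'
#' @param min_scale,max_scale Window-size range in samples.
#' @param n_scales Number of (unique) scales.
#' @return Integer vector of window sizes.
#' @export
dfa_scales <- function(min_scale = 300L, max_scale = 7200L, n_scales = 20L) {
  unique(round(exp(seq(log(min_scale), log(max_scale), length.out = n_scales))))
}

#' DFA fluctuation function
#'
#' The profile is the cumulative sum of the mean-removed series.  For each
#' window size `n` the profile is divided into `floor(N/n)` non-overlapping
#' windows from the start *and* the same number from the end (so the tail
#' beyond the last full start-anchored window still contributes), a
#' least-squares line is fitted in every window (first-order detrending,
#' DFA1), and `F(n)` is the root mean square of the residuals over all
#' covered points.
#'
#' @param values Numeric series (the 1 Hz movement series; the cumulative
#'   summation to a profile happens internally).
#' @param scales Integer window sizes; each must satisfy
#'   `4 <= scale <= length(values)/4`.
#' @return Tibble with columns `scale` and `fluctuation`.
#' @export
dfa_fluctuation <- function(values, scales = dfa_scales()) {
  assert_numeric_series(values, min_len = 16L)
  scales <- sort(unique(as.integer(scales)))
  N <- length(values)
  if (any(scales < 4L) || any(scales > N %/% 4L)) {
    abort(sprintf("scales must lie in [4, N/4] = [4, %d]", N %/% 4L))
  }
  y <- cumsum(values - mean(values))
  fl <- vapply(scales, function(n) {
    nw <- N %/% n
    starts <- c((seq_len(nw) - 1L) * n + 1L,          # anchored at the start
                N - (seq_len(nw)) * n + 1L)           # anchored at the end
    idx <- outer(0:(n - 1L), starts, "+")             # n x 2nw index matrix
    Y <- matrix(y[idx], nrow = n)
    k <- as.numeric(seq_len(n))
    nn <- as.numeric(n)
    sk <- nn * (nn + 1) / 2; skk <- nn * (nn + 1) * (2 * nn + 1) / 6
    sy <- colSums(Y); sky <- as.numeric(crossprod(k, Y))
    denom <- n * skk - sk^2
    b <- (n * sky - sk * sy) / denom                  # per-window slope
    a <- (sy - b * sk) / n                            # per-window intercept
    R <- Y - (rep(1, n) %o% a + k %o% b)
    sqrt(mean(R^2))
  }, numeric(1))
  tibble::tibble(scale = scales, fluctuation = fl)
}

#' Fit the DFA scaling exponent
#'
#' Ordinary least squares of `log10 F(n)` on `log10 n`, restricted to
#' scales inside `fit_range`; the slope is alpha.
#'
#' @param fluct Tibble from [dfa_fluctuation()] (columns `scale`,
#'   `fluctuation`).
#' @param fit_range Length-2 numeric range of scales (inclusive) used in
#'   the fit; default 300-7,200 samples (5 min-2 h at 1 Hz).
#' @return List with `alpha`, `r_squared`, `n_scales_used`.
#' @export
fit_alpha <- function(fluct, fit_range = c(300, 7200)) {
  keep <- fluct$scale >= fit_range[1] & fluct$scale <= fit_range[2] &
    fluct$fluctuation > 0
  if (sum(keep) < 4L) abort("fewer than 4 scales inside the fit range")
  lx <- log10(fluct$scale[keep]); ly <- log10(fluct$fluctuation[keep])
  fit <- lm(ly ~ lx)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(alpha = unname(coef(fit)[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_scales_used = sum(keep))
}

#' Detrended fluctuation analysis of a movement series
#'
#' Convenience wrapper: [dfa_fluctuation()] + [fit_alpha()].
#'
#' @inheritParams dfa_fluctuation
#' @inheritParams fit_alpha
#' @return A `dfa_result` object with `scales`, `fluctuation`, `alpha`,
#'   `r_squared`, `fit_range`.
#' @examples
#' r <- dfa(gen_gaussian_noise(4096, seed = 1), scales = dfa_scales(8, 1024))
#' r$alpha  # ~ 0.5 for white noise
#' @export
dfa <- function(values, scales = dfa_scales(), fit_range = range(scales)) {
  fl <- dfa_fluctuation(values, scales)
  fit <- fit_alpha(fl, fit_range)
  structure(
    list(scales = fl$scale, fluctuation = fl$fluctuation,
         alpha = fit$alpha, r_squared = fit$r_squared,
         fit_range = fit_range),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "DFA1: alpha = %.3f (R^2 = %.4f) over %d scales in [%g, %g] samples\n",
    x$alpha, x$r_squared, sum(x$scales >= x$fit_range[1] &
                                x$scales <= x$fit_range[2]),
    x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @export
tidy.dfa_result <- function(x, ...) {
  tibble::tibble(scale = x$scales, fluctuation = x$fluctuation)
}

#' @export
glance.dfa_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, r_squared = x$r_squared,
                 fit_min = x$fit_range[1], fit_max = x$fit_range[2])
}

#' @export
autoplot.dfa_result <- function(object, ...) {
  df <- tidy(object)
  in_fit <- df$scale >= object$fit_range[1] & df$scale <= object$fit_range[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$fluctuation)) +
    ggplot2::geom_point(ggplot2::aes(colour = in_fit)) +
    ggplot2::geom_smooth(data = df[in_fit, ], method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("grey60", "black"),
                                 guide = "none") +
    ggplot2::labs(x = "window size n (samples)", y = "F(n)",
                  title = sprintf("DFA1: alpha = %.2f", object$alpha)) +
    ggplot2::theme_minimal()
}
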