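# Irregularity / unpredictability measures: approximate entropy (ApEn),
# sample entropy (SampEn), and the time-resolved expanded sample entropy
# (expSampEn), with the multiscale moving-average protocol.
#
# Conventions (fixed so that the three measures are mutually consistent):
#   * "close" means Chebyshev distance <= r * SD (population SD, divisor N)
#     of the scale-averaged series;
#   * ApEn / expSampEn include the self-match, so every conditional
#     probability is > 0 and expSampEn is finite and >= 0 everywhere;
#   * SampEn excludes self-matches (the standard, less biased convention);
#   * natural logarithm throughout (values in nats);
#   * ApEn is the time average of the per-point conditional log-probability,
#     -<log p(x_n | x_n^-)>, so mean(expSampEn) == ApEn holds *exactly*
#     (this equals the classic Phi^m - Phi^{m+1} form up to O(1/N) edge
#     terms).

entropy_params <- function(values, m, r) {
  m <- as.integer(m)
  if (m < 1L) abort("`m` must be >= 1")
  if (r <= 0) abort("`r` must be > 0")
  tol <- r * pop_sd(values)
  if (tol == 0) abort("constant series: tolerance r * SD is zero")
  list(m = m, r = r, tol = tol)
}

#' Approximate entropy
#'
#' `-<log p(x_n | x_n^-)>`: the negative time-averaged log conditional
#' probability that the current value is close to a stored one given that
#' the preceding `m` values are close, with self-matches included.
#'
#' @param values Numeric series.
#' @param m Template length (default 2).
#' @param r Tolerance coefficient; matching tolerance is `r` times the
#'   population SD of `values` (default 0.2).
#' @return Approximate entropy in nats (a single non-negative value).
#' @export
apen <- function(values, m = 2L, r = 0.2) {
  assert_numeric_series(values, min_len = m + 2L)
  p <- entropy_params(values, m, r)
  eng <- entropy_engine(values, p$m, p$tol)
  mean(eng$exps)
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` is the number of pairs of `m`-length templates
#' within tolerance of each other and `A` the number of those pairs that
#' remain within tolerance when extended by one point; self-matches are
#' excluded.
#'
#' @inheritParams apen
#' @return Sample entropy in nats.  If no template pair extends (`A = 0`)
#'   the result is `Inf`; if no `m`-template pair matches at all the
#'   entropy is undefined and an error is raised.
#' @export
sampen <- function(values, m = 2L, r = 0.2) {
  assert_numeric_series(values, min_len = m + 2L)
  p <- entropy_params(values, m, r)
  eng <- entropy_engine(values, p$m, p$tol)
  if (eng$B == 0) abort("no m-template matches: sample entropy undefined")
  if (eng$A == 0) return(Inf)
  -log(eng$A / eng$B)
}

#' Expanded sample entropy (time-resolved irregularity)
#'
#' Per-time-point irregularity `-log p(x_n | x_n^-)`: how unpredictable the
#' value at time `n` is given the whole night's repertoire of length-`m`
#' patterns.  Counting conventions match [apen()], so the time average of
#' the output equals `apen(values, m, r)` exactly.
#'
#' @inheritParams apen
#' @return An `exp_sampen_series` object: `values` (length
#'   `length(values) - m`), `time_offset` (the index in the input series of
#'   the first output value, `m + 1`; output value `j` describes input index
#'   `j + m`), and `params`.
#' @export
exp_sampen <- function(values, m = 2L, r = 0.2) {
  assert_numeric_series(values, min_len = m + 2L)
  p <- entropy_params(values, m, r)
  eng <- entropy_engine(values, p$m, p$tol)
  structure(
    list(values = eng$exps, time_offset = p$m + 1L,
         params = list(m = p$m, r = p$r, tolerance_abs = p$tol)),
    class = "exp_sampen_series"
  )
}

#' @export
print.exp_sampen_series <- function(x, ...) {
  cat(sprintf(
    "expSampEn series: %d points (m = %d, r = %g), mean %.4f nats\n",
    length(x$values), x$params$m, x$params$r, mean(x$values)))
  invisible(x)
}

#' @export
tidy.exp_sampen_series <- function(x, ...) {
  tibble::tibble(t = seq_along(x$values) + x$time_offset - 1L,
                 value = x$values)
}

#' @export
autoplot.exp_sampen_series <- function(object, smooth = 1L, ...) {
  df <- tidy(object)
  if (smooth > 1L) {
    v <- moving_average(df$value, smooth)
    df <- tibble::tibble(t = df$t[seq_along(v) + smooth - 1L], value = v)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "expSampEn (nats)") +
    ggplot2::theme_minimal()
}

#' Multiscale entropy profile
#'
#' For each time scale the series is moving-averaged over the scale window
#' (trailing, valid mode), the tolerance is recomputed as `r` times the SD
#' of the *averaged* series, and ApEn, SampEn and expSampEn are computed on
#' it.  This is the moving-average multiscale protocol (not Costa-style
#' block coarse-graining).
#'
#' @inheritParams apen
#' @param scales Integer vector of scales in samples (default
#'   `c(30, 100, 300)`, i.e. seconds at 1 Hz).
#' @return Tibble with one row per scale: `scale`, `apen`, `sampen`,
#'   `exp_sampen` (list column of `exp_sampen_series`; each inherits the
#'   additional time offset `scale - 1` from the averaging window, recorded
#'   in its `time_offset`).
#' @export
multiscale_profile <- function(values, scales = c(30L, 100L, 300L),
                               m = 2L, r = 0.2) {
  scales <- as.integer(scales)
  if (any(scales < 1L)) abort("scales must be >= 1")
  assert_numeric_series(values, min_len = max(scales) + m + 2L)
  rows <- lapply(scales, function(s) {
    av <- moving_average(values, s)
    es <- exp_sampen(av, m = m, r = r)
    # stamp times in the coordinates of the *input* series: averaged sample
    # j sits at input time j + s - 1, and expSampEn starts at averaged
    # index m + 1
    es$time_offset <- es$time_offset + s - 1L
    sm <- tryCatch(sampen(av, m = m, r = r), error = function(e) NA_real_)
    tibble::tibble(scale = s, apen = mean(es$values), sampen = sm,
                   exp_sampen = list(es))
  })
  dplyr::bind_rows(rows)
}
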