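# Internal helpers shared across modules.

# Population standard deviation (divisor N).  Entropy tolerances and the
# FNN size test are normalized with this, so that both are invariant under
# positive affine transforms of the input regardless of N.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

assert_numeric_series <- function(x, min_len = 1L, name = "series") {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector without missing values", name))
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d samples (got %d)",
                  name, min_len, length(x)))
  }
  invisible(x)
}

# Deterministic 31-bit seed derived from a base seed and a label, used to
# give every recording / surrogate its own reproducible stream.  Simple
# multiplicative string hash folded into [0, 2^31 - 2]; arithmetic in
# doubles stays exact below 2^53.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(label)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer((h + 1) %% 2147483647)
}

# Trailing moving average, valid mode: output j = mean(x[j .. j + w - 1]),
# length N - w + 1.  This single primitive backs the multiscale entropy
# protocol, the FNN pre-averaging and the 60-min statistical smoothing.

#' Trailing moving average (valid mode)
#'
#' Averages `x` over a sliding window of `window` samples.  Output element
#' `j` is the mean of `x[j:(j + window - 1)]`, so the result has
#' `length(x) - window + 1` elements and no edge padding.  Element `j` of
#' the output is naturally stamped with the *end* of its window,
#' `j + window - 1`, which is the convention used when series at different
#' scales are aligned.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (`>= 1`, `<= length(x)`).
#' @return Numeric vector of length `length(x) - window + 1`.
#' @examples
#' moving_average(c(0, 1, 2, 3), 2)
#' @export
moving_average <- function(x, window) {
  assert_numeric_series(x)
  window <- as.integer(window)
  if (window < 1L) abort("`window` must be >= 1")
  if (window > length(x)) {
    abort(sprintf("`window` (%d) exceeds series length (%d)", window, length(x)))
  }
  if (window == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

# Evaluate a function under a temporary, restored RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
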