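# Preprocessing: raw tri-axial 32 Hz acceleration -> 1 Hz RMS magnitude
# series -> 8-h analysis window -> median-binarized series.

#' Resample a tri-axial recording to 1 Hz by block averaging
#'
#' Each output sample is the arithmetic mean of one non-overlapping block of
#' `sampling_rate` input samples per axis; a trailing partial block is
#' dropped.
#'
#' @param raw Data frame with columns `ax`, `ay`, `az` (acceleration in G),
#'   one row per sample at `sampling_rate` Hz.
#' @param sampling_rate Input sampling rate in Hz (default 32).
#' @return Tibble with columns `t` (seconds, 1-based block index), `ax`,
#'   `ay`, `az` at 1 Hz.
#' @export
block_average_resample <- function(raw, sampling_rate = 32) {
  if (!all(c("ax", "ay", "az") %in% names(raw))) {
    abort("`raw` must have columns ax, ay, az")
  }
  n <- nrow(raw)
  if (n < sampling_rate) abort("recording shorter than one resampling block")
  n_blocks <- n %/% sampling_rate
  grp <- rep(seq_len(n_blocks), each = sampling_rate)
  keep <- seq_len(n_blocks * sampling_rate)
  tibble::tibble(
    t  = seq_len(n_blocks),
    ax = as.numeric(tapply(raw$ax[keep], grp, mean)),
    ay = as.numeric(tapply(raw$ay[keep], grp, mean)),
    az = as.numeric(tapply(raw$az[keep], grp, mean))
  )
}

#' Zero-phase high-pass filter per axis
#'
#' Removes sustained (gravitational) components with a 4th-order Butterworth
#' high-pass applied forward and backward ([signal::filtfilt]), so the
#' filter has zero phase distortion.  At the default cutoff of 0.0028 Hz a
#' constant input is mapped to numerical zero while oscillations faster than
#' ten times the cutoff pass essentially unattenuated.
#'
#' @param series3d Data frame with columns `ax`, `ay`, `az` at `fs` Hz.
#' @param cutoff High-pass cutoff frequency in Hz.
#' @param fs Sampling rate of `series3d` in Hz (default 1, i.e. after
#'   [block_average_resample()]).
#' @return Tibble with the same columns, filtered.
#' @export
highpass <- function(series3d, cutoff = 0.0028, fs = 1) {
  if (!all(c("ax", "ay", "az") %in% names(series3d))) {
    abort("`series3d` must have columns ax, ay, az")
  }
  n <- nrow(series3d)
  if (n < 30L) abort("series too short for the high-pass filter warm-up")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  # odd-reflection padding suppresses the forward-backward edge transients
  # (the filter's slowest pole decays over ~fs/cutoff samples)
  npad <- min(n - 1L, as.integer(ceiling(10 * fs / cutoff)))
  out <- series3d
  for (axis in c("ax", "ay", "az")) {
    x <- series3d[[axis]]
    xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
    yf <- as.numeric(signal::filtfilt(bf, xp))
    out[[axis]] <- yf[(npad + 1L):(npad + n)]
  }
  tibble::as_tibble(out)
}

#' Combine three axes into one magnitude series (RMS)
#'
#' `value(t) = sqrt((ax^2 + ay^2 + az^2) / 3)` — the literal root mean
#' square over the three components.  This differs from the Euclidean norm
#' by the constant factor `sqrt(3)`; every downstream statistic in the
#' package is invariant under positive scaling, so the choice is fixed
#' purely for reproducibility.
#'
#' @param series3d Data frame with columns `ax`, `ay`, `az` (and optionally
#'   `t`, carried through).
#' @return Tibble with columns `t` and `value` (non-negative, in G).
#' @export
rms_combine <- function(series3d) {
  if (!all(c("ax", "ay", "az") %in% names(series3d))) {
    abort("`series3d` must have columns ax, ay, az")
  }
  lens <- vapply(series3d[c("ax", "ay", "az")], length, integer(1))
  if (length(unique(lens)) != 1L) abort("axes have unequal lengths")
  tibble::tibble(
    t = if ("t" %in% names(series3d)) series3d$t else seq_len(nrow(series3d)),
    value = sqrt((series3d$ax^2 + series3d$ay^2 + series3d$az^2) / 3)
  )
}

#' Locate the sleep-onset anchor
#'
#' Returns the first index `i` (1-based) such that all `run_length`
#' consecutive samples starting at `i` fall below `threshold`.  The anchor
#' is the *start* of the first qualifying quiescent run; the analysis
#' window is taken from there.
#'
#' @param values Numeric 1 Hz magnitude series (in G).
#' @param threshold Quiescence threshold in G (default 0.1).
#' @param run_length Required quiescent run in seconds (default 600, i.e.
#'   10 min).
#' @return Integer onset index.
#' @export
detect_sleep_onset <- function(values, threshold = 0.1, run_length = 600L) {
  assert_numeric_series(values, min_len = run_length)
  quiet <- values < threshold
  # windowed count of quiet samples; a full window means a qualifying run
  wsum <- moving_average(as.numeric(quiet), run_length) * run_length
  idx <- which(wsum > run_length - 0.5)
  if (length(idx) == 0L) {
    abort(sprintf("no run of %d s below %g G found (onset not detected)",
                  run_length, threshold))
  }
  idx[1]
}

#' Extract the fixed-duration analysis window
#'
#' @param values Numeric 1 Hz series.
#' @param onset Start index (1-based) from [detect_sleep_onset()].
#' @param duration Window length in samples (default 28,800 = 8 h at 1 Hz).
#' @return Numeric vector of exactly `duration` samples.
#' @export
extract_window <- function(values, onset, duration = 28800L) {
  assert_numeric_series(values)
  onset <- as.integer(onset); duration <- as.integer(duration)
  if (onset < 1L) abort("`onset` must be >= 1")
  if (onset + duration - 1L > length(values)) {
    abort(sprintf(
      "recording too short: need %d samples from onset %d, have %d",
      duration, onset, length(values)))
  }
  values[onset:(onset + duration - 1L)]
}

#' Binarize a movement series at its median
#'
#' Values strictly above the per-recording median map to 1, values at or
#' below it to 0.  The strict inequality means at most half of the samples
#' can be 1, and that for a heavily tied series (e.g. a sparse movement
#' trace sitting on a constant noise floor) the tied mass binarizes to 0.
#'
#' @param values Numeric movement magnitude series.
#' @return List with `values` (integer 0/1 vector) and `threshold` (the
#'   median used).  A constant input yields all zeros with a warning.
#' @export
binarize_median <- function(values) {
  assert_numeric_series(values)
  thr <- median(values)
  out <- as.integer(values > thr)
  if (all(out == 0L) && length(unique(values)) == 1L) {
    warn("constant series: binarization is degenerate (all zeros)")
  }
  list(values = out, threshold = thr)
}

#' Full preprocessing chain for a raw tri-axial recording
#'
#' [block_average_resample()] -> [highpass()] -> [rms_combine()] ->
#' [detect_sleep_onset()] -> [extract_window()].
#'
#' @inheritParams block_average_resample
#' @param onset_threshold,onset_run Passed to [detect_sleep_onset()].
#' @param duration Analysis-window length in seconds.
#' @param cutoff High-pass cutoff in Hz.
#' @return List with `values` (the windowed 1 Hz magnitude series),
#'   `onset_index`, and `full_series` (the pre-window 1 Hz series).
#' @export
preprocess_recording <- function(raw, sampling_rate = 32, cutoff = 0.0028,
                                 onset_threshold = 0.1, onset_run = 600L,
                                 duration = 28800L) {
  s1 <- block_average_resample(raw, sampling_rate)
  s1 <- highpass(s1, cutoff = cutoff, fs = 1)
  mag <- rms_combine(s1)
  onset <- detect_sleep_onset(mag$value, onset_threshold, onset_run)
  list(values = extract_window(mag$value, onset, duration),
       onset_index = onset,
       full_series = mag$value)
}
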