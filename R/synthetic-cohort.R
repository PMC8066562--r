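# Regime-switching synthetic actigraphy.  Real overnight accelerometry
# cannot be shared, so validation cohorts are generated: 1 Hz non-negative
# movement-magnitude series in which a two-state semi-Markov process
# alternates between a high-irregularity and a low-irregularity movement
# state, movement events arrive as a renewal process with state- and
# group-specific rate and interval variability, and event magnitudes are
# lognormal (heavy-tailed).  The group effect — lower irregularity of
# movement *occurrence* in group B — lives entirely in the inter-event
# interval coefficient of variation of the high-irregularity state.

#' Synthetic cohort generator configuration
#'
#' @param n_subjects_per_group Subjects per group (default 17).
#' @param nights_per_subject Nights recorded per subject (default 3).
#' @param series_length Samples per night at 1 Hz (default 28,800 = 8 h).
#' @param state_dwell_mean Mean parameter of the dwell-time distribution per
#'   irregularity state, seconds (default 5,400 = 90 min).
#' @param state_dwell_min,state_dwell_max Dwell times are exponential
#'   truncated to this range (defaults 4,500 s and 14,400 s, i.e. 75 min
#'   to 4 h), emulating ultradian state alternation: every full-length
#'   night contains several switches, no night is a single state, and
#'   every dwell is long enough to contain 60-min smoothing windows that
#'   lie entirely inside one state.
#' @param event_rate_high,event_rate_low Movement events per second in the
#'   high-/low-irregularity state (defaults 0.20 and 0.02).
#' @param interval_cv_high Named numeric `c(A = , B = )`: coefficient of
#'   variation of inter-event intervals in the high-irregularity state per
#'   group.  `B <= A` encodes the reduced-irregularity (ASD-like) effect;
#'   defaults `c(A = 1, B = 0.3)`.
#' @param interval_cv_low Interval CV in the low-irregularity state, both
#'   groups (default 1, i.e. a Poisson-like exponential renewal process).
#' @param magnitude_log_mean,magnitude_log_sd Lognormal parameters of event
#'   magnitudes in G (defaults `log(0.05)` and 1).
#' @param noise_floor Constant resting level in G added to non-event
#'   samples (default 0.001) so the series is never exactly constant and
#'   the median threshold separates events cleanly.
#' @param subject_sd_rate_high,subject_sd_rate_low,subject_sd_dwell
#'   Between-subject heterogeneity: each subject carries lognormal
#'   multipliers (sdlog given by these parameters, fixed across that
#'   subject's nights) on the high-state event rate, the low-state event
#'   rate and the dwell mean (defaults 0.05, 0.4 and 0.1).  Children differ
#'   far more in how much they move during quiet sleep than during active
#'   epochs, hence the much wider low-state spread.
#' @param seed Integer master seed; per-recording seeds are derived from it
#'   deterministically.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects_per_group = 17L,
                             nights_per_subject = 3L,
                             series_length = 28800L,
                             state_dwell_mean = 5400,
                             state_dwell_min = 4500,
                             state_dwell_max = 14400,
                             event_rate_high = 0.20,
                             event_rate_low = 0.02,
                             interval_cv_high = c(A = 1, B = 0.3),
                             interval_cv_low = 1,
                             magnitude_log_mean = log(0.05),
                             magnitude_log_sd = 1,
                             noise_floor = 0.001,
                             subject_sd_rate_high = 0.05,
                             subject_sd_rate_low = 0.4,
                             subject_sd_dwell = 0.1,
                             seed = 1L) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    nights_per_subject = as.integer(nights_per_subject),
    series_length = as.integer(series_length),
    state_dwell_mean = state_dwell_mean,
    state_dwell_min = state_dwell_min,
    state_dwell_max = state_dwell_max,
    event_rate_high = event_rate_high,
    event_rate_low = event_rate_low,
    interval_cv_high = interval_cv_high,
    interval_cv_low = interval_cv_low,
    magnitude_log_mean = magnitude_log_mean,
    magnitude_log_sd = magnitude_log_sd,
    noise_floor = noise_floor,
    subject_sd_rate_high = subject_sd_rate_high,
    subject_sd_rate_low = subject_sd_rate_low,
    subject_sd_dwell = subject_sd_dwell,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects_per_group < 1L) abort("need at least one subject per group")
  if (cfg$nights_per_subject < 1L) abort("need at least one night per subject")
  if (cfg$series_length < 1L) abort("`series_length` must be positive")
  if (cfg$state_dwell_mean <= 0) abort("`state_dwell_mean` must be positive")
  if (cfg$state_dwell_min <= 0 || cfg$state_dwell_max < cfg$state_dwell_min) {
    abort("dwell bounds must satisfy 0 < state_dwell_min <= state_dwell_max")
  }
  if (cfg$event_rate_high <= 0 || cfg$event_rate_low <= 0) {
    abort("event rates must be positive")
  }
  if (cfg$subject_sd_rate_high < 0 || cfg$subject_sd_rate_low < 0 ||
      cfg$subject_sd_dwell < 0) {
    abort("subject heterogeneity sdlogs must be >= 0")
  }
  if (!all(c("A", "B") %in% names(cfg$interval_cv_high))) {
    abort("`interval_cv_high` must be a named vector with entries A and B")
  }
  if (any(cfg$interval_cv_high <= 0) || cfg$interval_cv_low <= 0) {
    abort("interval CVs must be positive")
  }
  if (cfg$interval_cv_high["B"] > cfg$interval_cv_high["A"]) {
    abort("interval_cv_high[B] must be <= interval_cv_high[A] (the group-B effect lowers irregularity)")
  }
  structure(cfg, class = "generator_config")
}

# Exponential dwell truncated to [a, b] by inverse-CDF sampling.
rtrunc_exp <- function(n, mean, a, b) {
  u <- runif(n)
  fa <- exp(-a / mean); fb <- exp(-b / mean)
  -mean * log(fa - u * (fa - fb))
}

# Gamma-renewal event times on [0, len] with given rate and interval CV
# (gamma shape = 1/CV^2, mean interval = 1/rate).
renewal_events <- function(len, rate, cv) {
  shape <- 1 / cv^2
  scale <- cv^2 / rate  # mean interval = shape * scale = 1 / rate
  n_guess <- max(16L, ceiling(len * rate * 2 + 10 * sqrt(len * rate + 1)))
  iv <- rgamma(n_guess, shape = shape, scale = scale)
  tt <- cumsum(iv)
  while (sum(tt) == 0 || tt[length(tt)] < len) {
    iv2 <- rgamma(n_guess, shape = shape, scale = scale)
    tt <- c(tt, tt[length(tt)] + cumsum(iv2))
  }
  tt[tt <= len]
}

#' Generate one synthetic actigraphy night
#'
#' Draws a two-state semi-Markov regime path (exponential dwells), lays
#' down movement events as a gamma-renewal process within each state
#' (state- and group-specific rate and interval CV), assigns lognormal
#' magnitudes to event samples, and rests non-event samples on the constant
#' noise floor.
#'
#' @param config A [generator_config()].
#' @param group `"A"` or `"B"`.
#' @param seed Integer seed for this night.
#' @param traits Optional subject-trait list from [subject_traits()]
#'   (multipliers on the event rates and dwell mean, shared by all nights
#'   of one subject); `NULL` means population-average traits.
#' @return List with `values` (non-negative numeric series of
#'   `series_length` samples), `state` (integer vector, 1 = high-, 0 =
#'   low-irregularity), `group`, `seed`.
#' @export
gen_actigraphy_night <- function(config, group = c("A", "B"), seed,
                                 traits = NULL) {
  stopifnot(inherits(config, "generator_config"))
  group <- match.arg(group)
  if (is.null(traits)) {
    traits <- list(rate_high = 1, rate_low = 1, dwell = 1)
  }
  N <- config$series_length
  cv_high <- unname(config$interval_cv_high[group])
  rate_high <- config$event_rate_high * traits$rate_high
  rate_low <- config$event_rate_low * traits$rate_low
  dwell_mean <- config$state_dwell_mean * traits$dwell
  with_seed_(seed, {
    # regime path: alternating states, exponential dwells
    state_seq <- integer(0)
    cur <- rbinom(1, 1, 0.5)  # random initial state
    total <- 0L
    while (total < N) {
      dwell <- max(1L, round(rtrunc_exp(1, dwell_mean,
                                        config$state_dwell_min,
                                        config$state_dwell_max)))
      state_seq <- c(state_seq, rep(cur, dwell))
      total <- total + dwell
      cur <- 1L - cur
    }
    state <- state_seq[seq_len(N)]

    values <- rep(config$noise_floor, N)
    # lay events within each maximal state segment
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$lengths)) {
      len <- runs$lengths[i]
      if (runs$values[i] == 1L) {
        rate <- rate_high; cv <- cv_high
      } else {
        rate <- rate_low; cv <- config$interval_cv_low
      }
      ev <- renewal_events(len, rate, cv)
      if (length(ev) == 0) next
      idx <- starts[i] + pmin(len - 1L, floor(ev))
      mag <- rlnorm(length(idx), meanlog = config$magnitude_log_mean,
                    sdlog = config$magnitude_log_sd)
      # events landing on the same 1 s sample accumulate
      acc <- tapply(mag, idx, sum)
      values[as.integer(names(acc))] <- values[as.integer(names(acc))] + acc
    }
    list(values = values, state = state, group = group, seed = seed)
  })
}

#' Subject trait multipliers
#'
#' Draws one set of lognormal multipliers (median 1) for a subject:
#' `rate_high`, `rate_low` and `dwell`, applied to the corresponding
#' generator parameters for every night of that subject.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for this subject.
#' @return List with `rate_high`, `rate_low`, `dwell`.
#' @export
subject_traits <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed_(seed, list(
    rate_high = rlnorm(1, 0, config$subject_sd_rate_high),
    rate_low = rlnorm(1, 0, config$subject_sd_rate_low),
    dwell = rlnorm(1, 0, config$subject_sd_dwell)))
}

#' Generate a full two-group synthetic cohort
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort` object: `recordings`, a tibble with columns
#'   `group`, `subject`, `night`, `seed` and list columns `values` and
#'   `state`; plus `config`.
#' @examples
#' cfg <- generator_config(n_subjects_per_group = 2, nights_per_subject = 1,
#'                         series_length = 600, seed = 7)
#' coh <- gen_cohort(cfg)
#' nrow(coh$recordings)  # 2 groups x 2 subjects x 1 night = 4
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grid <- expand.grid(night = seq_len(config$nights_per_subject),
                      subject = seq_len(config$n_subjects_per_group),
                      group = c("A", "B"), stringsAsFactors = FALSE)
  rec <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$group[i]; s <- grid$subject[i]; nt <- grid$night[i]
    traits <- subject_traits(config, derive_seed(config$seed, g, s, "traits"))
    rs <- derive_seed(config$seed, g, s, nt)
    rec_night <- gen_actigraphy_night(config, group = g, seed = rs,
                                      traits = traits)
    tibble::tibble(group = g, subject = s, night = nt, seed = rs,
                   values = list(rec_night$values),
                   state = list(rec_night$state))
  })
  structure(list(recordings = dplyr::bind_rows(rec), config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic actigraphy cohort: 2 x %d subjects x %d nights = %d recordings of %d samples\n",
    x$config$n_subjects_per_group, x$config$nights_per_subject,
    nrow(x$recordings), x$config$series_length))
  invisible(x)
}

#' Expand a 1 Hz magnitude series to a raw tri-axial recording
#'
#' Thin up-sampler used to exercise the preprocessing chain end to end: the
#' magnitude is distributed isotropically over three axes, held constant
#' within each 1 s block of `sampling_rate` samples, and a constant 1 G
#' gravity offset is added to the z axis (which the high-pass filter must
#' remove).  No attempt is made to simulate 32 Hz within-second dynamics.
#'
#' @param values 1 Hz magnitude series.
#' @param sampling_rate Output rate in Hz (default 32).
#' @param gravity Constant offset added to `az` in G (default 1).
#' @return Tibble with columns `t` (seconds), `ax`, `ay`, `az`.
#' @export
upsample_to_triaxial <- function(values, sampling_rate = 32L, gravity = 1) {
  assert_numeric_series(values)
  per_axis <- values  # equal magnitude on each axis keeps the 3-axis RMS = values
  n <- length(values) * sampling_rate
  tibble::tibble(
    t = rep(seq_along(values), each = sampling_rate),
    ax = rep(per_axis, each = sampling_rate),
    ay = rep(per_axis, each = sampling_rate),
    az = rep(per_axis, each = sampling_rate) + gravity
  )
}
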