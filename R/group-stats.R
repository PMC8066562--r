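# Cohort-level statistics: pointwise two-group t-tests on smoothed
# irregularity tracks, high/low-irregularity representative values, and
# Spearman cross-measure correlation tables.
#
# Conventions of the reference protocol, kept deliberately: classic
# equal-variance Student's t-tests; one-tailed p-values in the
# "group B lower" direction for the group comparisons (the convention the
# published T/p pairs imply); NO multiple-comparison correction on the
# pointwise tracks (which inflates familywise error — the tracks are
# descriptive).

#' 60-minute smoothing of a statistic track
#'
#' Trailing 3,600-sample moving average (valid mode), the smoothing applied
#' to every series before the group statistics.
#'
#' @param values Numeric series at 1 Hz (length > 3,600).
#' @param window Smoothing window in samples (default 3,600 = 60 min).
#' @return Numeric vector of length `length(values) - window + 1`.
#' @export
smooth_60min <- function(values, window = 3600L) {
  if (length(values) < window) abort("series shorter than the smoothing window")
  moving_average(values, window)
}

#' Pointwise two-group t-test track
#'
#' At every time point, an equal-variance two-sample Student's t-test of
#' group A versus group B across subjects (each subject contributes one
#' smoothed series, nights having been averaged within subject first).
#' `p_value` is the one-tailed probability in the B-lower-than-A direction
#' (`t > 0` favors A > B); no multiple-comparison correction is applied.
#'
#' @param data Tibble with columns `group` (two levels), `subject`, `time`,
#'   `value`; one value per subject per time point.
#' @param ref Label of the reference group "A" (default: first sorted
#'   level).
#' @param level Significance level for the `significant_lower_B` track
#'   (default 0.05).
#' @return Tibble with columns `time`, `t_stat`, `p_value`,
#'   `significant_lower_B`.
#' @export
pointwise_group_ttest <- function(data, ref = NULL, level = 0.05) {
  need <- c("group", "subject", "time", "value")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns group, subject, time, value")
  }
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2L) abort("`data` must contain exactly two groups")
  if (is.null(ref)) ref <- groups[1]
  other <- setdiff(groups, ref)

  wide_a <- series_matrix(data[data$group == ref, ])
  wide_b <- series_matrix(data[data$group == other, ])
  if (!identical(wide_a$time, wide_b$time)) {
    abort("the two groups are on different time supports")
  }
  na <- ncol(wide_a$m); nb <- ncol(wide_b$m)
  if (na < 3L || nb < 3L) abort("need at least 3 subjects per group")

  ma <- rowMeans(wide_a$m); mb <- rowMeans(wide_b$m)
  va <- apply(wide_a$m, 1, var); vb <- apply(wide_b$m, 1, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- pt(t_stat, df = na + nb - 2, lower.tail = FALSE)
  tibble::tibble(time = wide_a$time, t_stat = t_stat, p_value = p,
                 significant_lower_B = p < level)
}

# subjects-as-columns matrix on the common time support
series_matrix <- function(df) {
  wide <- tidyr::pivot_wider(df[c("subject", "time", "value")],
                             names_from = "subject", values_from = "value")
  wide <- wide[order(wide$time), ]
  m <- as.matrix(wide[-1])
  if (anyNA(m)) abort("subjects have unequal time supports")
  list(time = wide$time, m = m)
}

#' High/low-irregularity representative values
#'
#' The 90th and 10th percentiles (linear interpolation between order
#' statistics, i.e. `quantile(type = 7)`) of a smoothed expSampEn track:
#' per-recording representatives of the high- and low-irregularity states
#' of the phasic irregularity profile.
#'
#' @param values Smoothed expSampEn track (numeric, non-empty).
#' @param q_high,q_low Percentiles in (0, 100) (defaults 90 and 10).
#' @return Tibble with columns `p_high` and `p_low`.
#' @export
representative_values <- function(values, q_high = 90, q_low = 10) {
  assert_numeric_series(values)
  qs <- quantile(values, c(q_high, q_low) / 100, names = FALSE, type = 7)
  tibble::tibble(p_high = qs[1], p_low = qs[2])
}

#' Two-group t-test on representative values
#'
#' Equal-variance Student's t-test of group A versus group B on
#' per-subject representative values; by default the p-value is one-tailed
#' in the A-greater-than-B direction (positive `t` means A > B).
#'
#' @param group_a,group_b Numeric vectors of per-subject values.
#' @param one_tailed One-tailed p in the A > B direction (default `TRUE`);
#'   otherwise two-sided.
#' @return Tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
representative_ttest <- function(group_a, group_b, one_tailed = TRUE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 3L || nb < 3L) abort("need at least 3 values per group")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) abort("zero pooled variance: t-test degenerate")
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- if (one_tailed) pt(t_stat, df, lower.tail = FALSE)
       else 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  tibble::tibble(t = t_stat, df = df, p_value = p,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Spearman correlations between aligned series
#'
#' Smooths each input series over `smoothing` samples, aligns all series on
#' their common time support using their `t` stamps, and computes the
#' per-recording Spearman rank correlation for each requested pair.  Input
#' series are tibbles with columns `t` and `value` (e.g. from
#' `tidy(exp_sampen(...))`); time stamps refer to a common clock.
#'
#' @param series Named list of tibbles with columns `t`, `value`.
#' @param pairs Two-column character matrix or data frame of series names
#'   to correlate; default: all unordered pairs.
#' @param smoothing Smoothing window in samples (default 3,600); `1`
#'   disables smoothing.
#' @return Tibble with columns `pair`, `a`, `b`, `rho`, `n` (`rho` is `NA`
#'   for a constant member).
#' @export
spearman_pairs <- function(series, pairs = NULL, smoothing = 3600L) {
  stopifnot(is.list(series), !is.null(names(series)))
  sm <- lapply(series, function(s) {
    if (!all(c("t", "value") %in% names(s))) {
      abort("each series must have columns t and value")
    }
    if (smoothing > 1L) {
      v <- moving_average(s$value, smoothing)
      tibble::tibble(t = s$t[seq_along(v) + smoothing - 1L], value = v)
    } else s
  })
  if (is.null(pairs)) {
    nm <- names(series)
    pairs <- t(utils::combn(nm, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("a", "b")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- sm[[pairs$a[i]]]; b <- sm[[pairs$b[i]]]
    common <- intersect(a$t, b$t)
    av <- a$value[match(common, a$t)]
    bv <- b$value[match(common, b$t)]
    rho <- if (length(common) < 3L || pop_sd(av) == 0 || pop_sd(bv) == 0) {
      NA_real_
    } else {
      cor(av, bv, method = "spearman")
    }
    tibble::tibble(pair = paste(pairs$a[i], pairs$b[i], sep = "-"),
                   a = pairs$a[i], b = pairs$b[i],
                   rho = rho, n = length(common))
  })
  dplyr::bind_rows(rows)
}

#' Cohort Spearman correlation table
#'
#' Aggregates per-recording [spearman_pairs()] results to the mean and SD
#' of the correlation per pair (and per any other grouping column present,
#' e.g. `scale`) — the structure of a cross-measure correlation table.
#'
#' @param per_recording Tibble: stacked [spearman_pairs()] outputs with at
#'   least columns `pair` and `rho` (plus e.g. `recording`, `scale`).
#' @return Tibble with columns `pair` (and `scale` if present),
#'   `rho_mean`, `rho_sd`, `n_recordings`.
#' @export
spearman_table <- function(per_recording) {
  if (!all(c("pair", "rho") %in% names(per_recording))) {
    abort("`per_recording` must have columns pair and rho")
  }
  keys <- intersect(c("pair", "scale"), names(per_recording))
  dplyr::summarise(
    dplyr::group_by(per_recording, dplyr::across(dplyr::all_of(keys))),
    rho_mean = mean(.data$rho, na.rm = TRUE),
    rho_sd = sd(.data$rho, na.rm = TRUE),
    n_recordings = sum(!is.na(.data$rho)),
    .groups = "drop")
}
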