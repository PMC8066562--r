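# End-to-end orchestration: configuration, series/manifest I/O, the
# per-recording analysis chain, and cohort-level aggregation.

#' Pipeline configuration
#'
#' All analysis constants in one validated list, with the reference
#' protocol's defaults: entropy m = 2, r = 0.2 at scales 30/100/300 s; FNN
#' thresholds A = 10, B = 2 with Theiler window = delay; 20 surrogates;
#' DFA fit range 5 min-2 h; onset threshold 0.1 G over 10 min; 60-min
#' (3,600 s) statistical smoothing; significance level 0.05.  Unknown keys
#' are rejected.
#'
#' @param ... Overrides of the defaults, e.g. `scales = c(30, 100)`,
#'   `surrogates = list(n = 5)`.  Sub-lists are merged key by key.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1L) {
  defaults <- list(
    m = 2L, r = 0.2,
    scales = c(30L, 100L, 300L),
    fnn = list(enabled = TRUE, d_max = 10L, A = 10, B = 2),
    surrogates = list(enabled = TRUE, n = 20L, max_iter = 100L),
    dfa = list(fit_min = 300L, fit_max = 7200L, n_scales = 20L),
    onset = list(detect = FALSE, threshold = 0.1, run_length = 600L,
                 duration = 28800L),
    stationarity = list(bins_raw = 5L, bins_thr = 2L),
    smoothing = 3600L,
    level = 0.05,
    seed = as.integer(seed)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  for (k in names(over)) {
    if (is.list(defaults[[k]]) && is.list(over[[k]])) {
      badsub <- setdiff(names(over[[k]]), names(defaults[[k]]))
      if (length(badsub) > 0) {
        abort(paste0("unknown key(s) in `", k, "`: ",
                     paste(badsub, collapse = ", ")))
      }
      defaults[[k]] <- modifyList(defaults[[k]], over[[k]])
    } else {
      defaults[[k]] <- over[[k]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly through [pipeline_config()]; unknown
#' keys in the file are rejected.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a movement series as delimited text
#'
#' Two-column CSV with header `t,value` (`t` in seconds, `value` in G).
#'
#' @param values Numeric series.
#' @param path File path.
#' @param t Optional time stamps (default `seq_along(values)`).
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a tibble with columns `t`, `value` (or `t`, `ax`, `ay`, `az`
#'   for a tri-axial file).
#' @export
write_series <- function(values, path, t = seq_along(values)) {
  write.csv(data.frame(t = t, value = values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read.csv(path)
  if (!("t" %in% names(df)) ||
      !(all(c("ax", "ay", "az") %in% names(df)) || "value" %in% names(df))) {
    abort(sprintf("unrecognized series file format: %s", path))
  }
  tibble::as_tibble(df)
}

#' Write a synthetic demo cohort to disk
#'
#' Generates a cohort with [gen_cohort()] and writes one series file per
#' recording plus a `manifest.csv` (columns `group`, `subject`, `night`,
#' `path`, `seed`).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (required: all stochastic entry points take an
#'   explicit seed).
#' @param config Optional [generator_config()]; defaults to the study-sized
#'   configuration with the given seed.
#' @return The manifest tibble, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
make_synthetic_demo <- function(out_dir, seed, config = NULL) {
  if (missing(seed)) abort("`seed` is required (explicit-seed policy)")
  if (is.null(config)) config <- generator_config(seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- gen_cohort(config)
  rec <- coh$recordings
  paths <- file.path(out_dir, sprintf("%s_s%02d_n%d.csv",
                                      rec$group, rec$subject, rec$night))
  for (i in seq_len(nrow(rec))) write_series(rec$values[[i]], paths[i])
  manifest <- tibble::tibble(group = rec$group, subject = rec$subject,
                             night = rec$night, path = paths, seed = rec$seed)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# single-recording analysis

#' Analyze one movement recording
#'
#' Runs the per-recording stages on an already-windowed 1 Hz magnitude
#' series: median binarization, the chi-square stationarity screen,
#' multiscale entropy (ApEn/SampEn/expSampEn) and DFA on both the raw and
#' the thresholded series, and (optionally) IAAFT surrogate metrics.
#' FNN needs a cohort-level delay and is run by [run_pipeline()].
#'
#' @param values 1 Hz movement magnitude series.
#' @param config A [pipeline_config()].
#' @param seed Seed for the surrogate stage.
#' @return List of result tibbles: `stationarity`, `entropy`, `dfa`,
#'   `surrogates` (NULL if disabled), plus `binary` (the thresholded
#'   series) and `threshold`.
#' @export
analyze_recording <- function(values, config = pipeline_config(),
                              seed = config$seed) {
  assert_numeric_series(values, min_len = 32L)
  bin <- binarize_median(values)
  datasets <- list(raw = values, thr = as.numeric(bin$values))

  stat_rows <- dplyr::bind_rows(lapply(names(datasets), function(ty) {
    nb <- if (ty == "raw") config$stationarity$bins_raw else config$stationarity$bins_thr
    # the bin-collapse fallback is recorded in the n_bins column; no need
    # to repeat the warning once per recording
    res <- tryCatch(tidy(suppressWarnings(
      stationarity_chi2(datasets[[ty]], nb, config$level))),
                    error = function(e) tibble::tibble(
                      statistic = NA_real_, dof = NA_integer_,
                      p_value = NA_real_, rejected = NA, n_bins = NA_integer_))
    dplyr::mutate(res, data_type = ty, .before = 1)
  }))

  ent_rows <- dplyr::bind_rows(lapply(names(datasets), function(ty) {
    prof <- multiscale_profile(datasets[[ty]], scales = config$scales,
                               m = config$m, r = config$r)
    dplyr::mutate(prof, data_type = ty, .before = 1)
  }))

  N <- length(values)
  dfa_rows <- dplyr::bind_rows(lapply(names(datasets), function(ty) {
    sc <- dfa_scales(min(config$dfa$fit_min, N %/% 8L),
                     min(config$dfa$fit_max, N %/% 4L),
                     config$dfa$n_scales)
    res <- dfa(datasets[[ty]], scales = sc, fit_range = range(sc))
    dplyr::mutate(glance(res), data_type = ty, .before = 1)
  }))

  surr_rows <- NULL
  if (isTRUE(config$surrogates$enabled)) {
    surr_rows <- dplyr::bind_rows(lapply(names(datasets), function(ty) {
      x <- datasets[[ty]]
      ens <- surrogate_ensemble(x, n = config$surrogates$n,
                                seed = derive_seed(seed, "surr", ty),
                                max_iter = config$surrogates$max_iter)
      dplyr::bind_rows(lapply(config$scales, function(s) {
        orig_av <- moving_average(x, s)
        o_samp <- tryCatch(sampen(orig_av, config$m, config$r),
                           error = function(e) NA_real_)
        o_ap <- apen(orig_av, config$m, config$r)
        surr_stats <- vapply(ens$surrogates, function(sv) {
          sav <- moving_average(sv, s)
          c(tryCatch(sampen(sav, config$m, config$r),
                     error = function(e) NA_real_),
            apen(sav, config$m, config$r))
        }, numeric(2))
        tibble::tibble(data_type = ty, scale = s,
                       sampen_original = o_samp, apen_original = o_ap,
                       sampen_surrogate_mean = mean(surr_stats[1, ], na.rm = TRUE),
                       apen_surrogate_mean = mean(surr_stats[2, ], na.rm = TRUE),
                       n_surrogates = length(ens$surrogates))
      }))
    }))
  }

  list(stationarity = stat_rows, entropy = ent_rows, dfa = dfa_rows,
       surrogates = surr_rows, binary = bin$values, threshold = bin$threshold)
}

# ---------------------------------------------------------------------------
# cohort pipeline

#' Run the full cohort pipeline
#'
#' For every manifest recording: load, (optionally) anchor and window,
#' binarize, then run the stationarity screen, multiscale entropy, DFA and
#' surrogate stages; select the cohort embedding delay as the median
#' autocorrelation time per data type and run FNN; finally compute the
#' group statistics (pointwise t-test tracks on 60-min-smoothed expSampEn,
#' 90th/10th-percentile representative values and their one-tailed t-tests,
#' Spearman cross-measure tables, and paired original-vs-surrogate tests).
#' A failing stage marks the recording's status and the run continues.
#'
#' @param config A [pipeline_config()].
#' @param manifest Tibble with columns `group`, `subject`, `night`, `path`
#'   (as written by [make_synthetic_demo()]), or with a list column
#'   `values` for in-memory cohorts (e.g. `gen_cohort(cfg)$recordings`).
#' @param progress Print per-recording progress lines (default `FALSE`).
#' @return A `cohort_result` list of tibbles: `recordings`, `stationarity`,
#'   `delays`, `fnn`, `entropy`, `dfa`, `surrogates`, `representatives`,
#'   `representative_tests`, `pointwise_tests`, `spearman`, plus `config`.
#' @export
run_pipeline <- function(config, manifest, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(manifest) == 0L) abort("empty manifest")
  need <- c("group", "subject", "night")
  if (!all(need %in% names(manifest))) {
    abort("manifest needs columns group, subject, night and path (or values)")
  }

  res <- list(stationarity = list(), entropy = list(), dfa = list(),
              surrogates = list(), tracks = list(), delays = list())
  status <- character(nrow(manifest))
  series_store <- vector("list", nrow(manifest))

  for (i in seq_len(nrow(manifest))) {
    rid <- sprintf("%s_s%02d_n%d", manifest$group[i], manifest$subject[i],
                   manifest$night[i])
    t0 <- Sys.time()
    out <- tryCatch({
      values <- load_recording(manifest, i, config)
      an <- analyze_recording(values, config,
                              seed = derive_seed(config$seed, "rec", rid))
      list(values = values, an = an)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      status[i] <- paste0("failed: ", conditionMessage(out))
      if (progress) message(sprintf("[%s] FAILED (%s)", rid, status[i]))
      next
    }
    status[i] <- "ok"
    an <- out$an
    key <- tibble::tibble(recording = rid, group = manifest$group[i],
                          subject = manifest$subject[i],
                          night = manifest$night[i])
    res$stationarity[[rid]] <- dplyr::bind_cols(key[rep(1, nrow(an$stationarity)), ],
                                                an$stationarity)
    res$entropy[[rid]] <- dplyr::bind_cols(
      key[rep(1, nrow(an$entropy)), ],
      dplyr::select(an$entropy, -"exp_sampen"))
    res$dfa[[rid]] <- dplyr::bind_cols(key[rep(1, nrow(an$dfa)), ], an$dfa)
    if (!is.null(an$surrogates)) {
      res$surrogates[[rid]] <- dplyr::bind_cols(key[rep(1, nrow(an$surrogates)), ],
                                                an$surrogates)
    }
    res$tracks[[rid]] <- dplyr::bind_cols(
      key[rep(1, nrow(an$entropy)), ],
      an$entropy[c("data_type", "scale", "exp_sampen")])
    res$delays[[rid]] <- dplyr::bind_cols(
      key,
      tibble::tibble(
        act_raw = tryCatch(autocorr_time(out$values), error = function(e) NA_integer_),
        act_thr = tryCatch(autocorr_time(as.numeric(an$binary)),
                           error = function(e) NA_integer_)))
    series_store[[i]] <- list(raw = out$values, thr = as.numeric(an$binary))
    if (progress) {
      message(sprintf("[%s] ok (%.1f s)", rid,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }

  recordings <- dplyr::mutate(manifest, status = status)
  delays <- dplyr::bind_rows(res$delays)
  if (nrow(delays) == 0L) abort("no recording could be analyzed")

  tau <- list(raw = median_delay(delays$act_raw[!is.na(delays$act_raw)]),
              thr = median_delay(delays$act_thr[!is.na(delays$act_thr)]))

  fnn_rows <- NULL
  if (isTRUE(config$fnn$enabled)) {
    fnn_rows <- dplyr::bind_rows(lapply(which(status == "ok"), function(i) {
      rid <- sprintf("%s_s%02d_n%d", manifest$group[i], manifest$subject[i],
                     manifest$night[i])
      dplyr::bind_rows(lapply(c("raw", "thr"), function(ty) {
        curve <- tryCatch(
          fnn_fractions(series_store[[i]][[ty]], tau = tau[[ty]],
                        d_max = config$fnn$d_max, A = config$fnn$A,
                        B = config$fnn$B),
          error = function(e) NULL)
        if (is.null(curve)) return(NULL)
        dplyr::mutate(tibble::as_tibble(curve), recording = rid,
                      data_type = ty, .before = 1)
      }))
    }))
  }

  gs <- cohort_group_stats(res$tracks, config)
  sp_table <- cohort_spearman(res$tracks, series_store, status, manifest, config)
  surr_tbl <- if (length(res$surrogates)) dplyr::bind_rows(res$surrogates) else NULL

  structure(
    list(recordings = recordings,
         stationarity = dplyr::bind_rows(res$stationarity),
         delays = list(per_recording = delays, tau = tau),
         fnn = fnn_rows,
         entropy = dplyr::bind_rows(res$entropy),
         dfa = dplyr::bind_rows(res$dfa),
         surrogates = surr_tbl,
         surrogate_tests = if (!is.null(surr_tbl)) surrogate_group_tests(surr_tbl),
         representatives = gs$representatives,
         representative_tests = gs$representative_tests,
         pointwise_tests = gs$pointwise_tests,
         spearman = sp_table,
         config = config),
    class = "cohort_result"
  )
}

load_recording <- function(manifest, i, config) {
  if ("values" %in% names(manifest)) {
    values <- manifest$values[[i]]
  } else {
    df <- read_series(manifest$path[i])
    if (all(c("ax", "ay", "az") %in% names(df))) {
      return(preprocess_recording(df,
                                  onset_threshold = config$onset$threshold,
                                  onset_run = config$onset$run_length,
                                  duration = config$onset$duration)$values)
    }
    values <- df$value
  }
  if (isTRUE(config$onset$detect)) {
    onset <- detect_sleep_onset(values, config$onset$threshold,
                                config$onset$run_length)
    values <- extract_window(values, onset, config$onset$duration)
  }
  values
}

# Per-recording smoothed expSampEn tracks -> representatives, pointwise
# tracks and Spearman tables.
cohort_group_stats <- function(tracks, config) {
  tr <- dplyr::bind_rows(tracks)
  if (nrow(tr) == 0L) return(list())
  sm_win <- config$smoothing

  smoothed <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
    es <- tr$exp_sampen[[i]]
    df <- tidy(es)
    if (nrow(df) < sm_win) return(NULL)
    v <- moving_average(df$value, sm_win)
    tibble::tibble(recording = tr$recording[i], group = tr$group[i],
                   subject = tr$subject[i], night = tr$night[i],
                   data_type = tr$data_type[i], scale = tr$scale[i],
                   t = list(df$t[seq_along(v) + sm_win - 1L]),
                   value = list(v))
  }))
  if (nrow(smoothed) == 0L) {
    warn("tracks shorter than the smoothing window: group statistics skipped")
    return(list())
  }

  # representatives (thresholded-data tracks define the irregularity states)
  reps <- dplyr::bind_rows(lapply(seq_len(nrow(smoothed)), function(i) {
    dplyr::bind_cols(smoothed[i, c("recording", "group", "subject", "night",
                                   "data_type", "scale")],
                     representative_values(smoothed$value[[i]]))
  }))

  rep_subject <- dplyr::summarise(
    dplyr::group_by(reps, .data$group, .data$subject, .data$data_type,
                    .data$scale),
    p_high = mean(.data$p_high), p_low = mean(.data$p_low), .groups = "drop")

  rep_tests <- dplyr::bind_rows(lapply(
    split(rep_subject, rep_subject[c("data_type", "scale")], drop = TRUE),
    function(d) {
      a <- d[d$group == "A", ]; b <- d[d$group == "B", ]
      if (nrow(a) < 3L || nrow(b) < 3L) return(NULL)
      dplyr::bind_rows(
        dplyr::mutate(representative_ttest(a$p_high, b$p_high),
                      state = "high", .before = 1),
        dplyr::mutate(representative_ttest(a$p_low, b$p_low),
                      state = "low", .before = 1)) |>
        dplyr::mutate(data_type = d$data_type[1], scale = d$scale[1],
                      .before = 1)
    }))

  # pointwise tracks: average nights within subject on the common support
  pw <- dplyr::bind_rows(lapply(
    split(smoothed, smoothed[c("data_type", "scale")], drop = TRUE),
    function(d) {
      long <- dplyr::bind_rows(lapply(seq_len(nrow(d)), function(i) {
        tibble::tibble(group = d$group[i], subject = d$subject[i],
                       time = d$t[[i]], value = d$value[[i]])
      }))
      bysub <- dplyr::summarise(
        dplyr::group_by(long, .data$group, .data$subject, .data$time),
        value = mean(.data$value), .groups = "drop")
      res <- tryCatch(pointwise_group_ttest(bysub, ref = "A",
                                            level = config$level),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::mutate(res, data_type = d$data_type[1], scale = d$scale[1],
                    .before = 1)
    }))

  list(representatives = reps, representative_tests = rep_tests,
       pointwise_tests = pw)
}

# Cross-measure Spearman table: per recording and scale, the correlations
# between the 60-min-smoothed raw series, thresholded series, and their
# expSampEn tracks.
cohort_spearman <- function(tracks, series_store, status, manifest, config) {
  rows <- lapply(which(status == "ok"), function(i) {
    rid <- sprintf("%s_s%02d_n%d", manifest$group[i], manifest$subject[i],
                   manifest$night[i])
    tr <- tracks[[rid]]
    sto <- series_store[[i]]
    dplyr::bind_rows(lapply(unique(tr$scale), function(s) {
      esr <- tr$exp_sampen[tr$data_type == "raw" & tr$scale == s][[1]]
      est <- tr$exp_sampen[tr$data_type == "thr" & tr$scale == s][[1]]
      ser <- list(
        raw = tibble::tibble(t = seq_along(sto$raw), value = sto$raw),
        thr = tibble::tibble(t = seq_along(sto$thr), value = sto$thr),
        raw_exps = tidy(esr),
        thr_exps = tidy(est))
      pairs <- rbind(c("raw", "thr"),
                     c("raw", "raw_exps"),
                     c("thr", "thr_exps"),
                     c("raw", "thr_exps"),
                     c("raw_exps", "thr_exps"))
      sp <- tryCatch(
        spearman_pairs(ser, pairs = pairs, smoothing = config$smoothing),
        error = function(e) NULL)
      if (is.null(sp)) return(NULL)
      dplyr::mutate(sp, recording = rid, scale = s, .before = 1)
    }))
  })
  per_rec <- dplyr::bind_rows(rows)
  if (nrow(per_rec) == 0L) return(NULL)
  list(per_recording = per_rec, table = spearman_table(per_rec))
}

surrogate_group_tests <- function(surr_tbl) {
  dplyr::bind_rows(lapply(
    split(surr_tbl, surr_tbl[c("data_type", "scale")], drop = TRUE),
    function(d) {
      ok <- !is.na(d$sampen_original) & !is.na(d$sampen_surrogate_mean)
      if (sum(ok) < 3L) return(NULL)
      dplyr::bind_rows(
        dplyr::mutate(compare_original_vs_surrogates(
          d$sampen_original[ok], d$sampen_surrogate_mean[ok]),
          metric = "sampen", .before = 1),
        dplyr::mutate(compare_original_vs_surrogates(
          d$apen_original[ok], d$apen_surrogate_mean[ok]),
          metric = "apen", .before = 1)) |>
        dplyr::mutate(data_type = d$data_type[1], scale = d$scale[1],
                      .before = 1)
    }))
}

#' @export
print.cohort_result <- function(x, ...) {
  ok <- sum(x$recordings$status == "ok")
  cat(sprintf("Cohort analysis: %d/%d recordings analyzed\n",
              ok, nrow(x$recordings)))
  cat(sprintf("  embedding delays tau: raw %d s, thresholded %d s\n",
              x$delays$tau$raw, x$delays$tau$thr))
  if (!is.null(x$representative_tests) && nrow(x$representative_tests)) {
    cat("  representative-value t-tests (thresholded data):\n")
    d <- x$representative_tests[x$representative_tests$data_type == "thr", ]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    scale %3d s, %4s state: T = %5.2f, one-tailed p = %.3f\n",
                  d$scale[i], d$state[i], d$t[i], d$p_value[i]))
    }
  }
  invisible(x)
}
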