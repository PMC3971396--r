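# total length of the union of intervals (matrix n x 2), clipped to span
.union_length <- function(ints, span) {
  if (is.null(ints) || nrow(ints) == 0) return(0)
  a <- pmax(ints[, 1], span[1])
  b <- pmin(ints[, 2], span[2])
  keep <- b > a
  if (!any(keep)) return(0)
  a <- a[keep]; b <- b[keep]
  o <- order(a)
  a <- a[o]; b <- b[o]
  tot <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_b) {
      tot <- tot + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    } else cur_b <- max(cur_b, b[i])
  }
  tot + (cur_b - cur_a)
}

.rec_info <- function(x) {
  if (inherits(x, "eeg_recording")) {
    list(onsets = x$annotations$onset_s, duration_s = recording_duration(x))
  } else if (inherits(x, "coupling_map")) {
    list(onsets = x$annotations$onset_s, duration_s = x$duration_s)
  } else stop("expected an eeg_recording or coupling_map")
}

#' Split a recording into training and testing spans
#'
#' The training span runs from the record start to the later of (a) the
#' onset of the `n_train_seizures`-th seizure plus the maximum preictal
#' duration and (b) `min_train_h` hours; the testing span is the remainder.
#'
#' @param x an `eeg_recording` (or `coupling_map`) with seizure annotations.
#' @param n_train_seizures seizures used for training (default 4).
#' @param min_train_h minimum training duration, hours (default 10).
#' @param sop_max_min largest preictal duration on the search grid, minutes
#'   (default 60); appended after the last training seizure so its
#'   post-seizure dynamics never leak into the test span.
#' @return list with `train` and `test`, each `c(start_s, end_s)`.
#' @export
split_train_test <- function(x, n_train_seizures = 4, min_train_h = 10,
                             sop_max_min = 60) {
  info <- .rec_info(x)
  if (length(info$onsets) < n_train_seizures + 1) {
    stop("patient unevaluable: needs more than ", n_train_seizures,
         " seizures for a train/test split")
  }
  t_split <- max(info$onsets[n_train_seizures] + sop_max_min * 60,
                 min_train_h * 3600)
  if (t_split >= info$duration_s) {
    stop("patient unevaluable: no recording left for a test span")
  }
  list(train = c(0, t_split), test = c(t_split, info$duration_s))
}

#' Sensitivity and false prediction rate of an alarm series
#'
#' A seizure counts as predicted when at least one alarm falls in its
#' preictal window `[onset - sop, onset)`; an alarm whose seizure-occurrence
#' period `(t, t + sop]` contains no onset is a false prediction. The false
#' prediction rate divides the false alarms by the time in which a false
#' alarm could have been raised: the span duration minus the union of
#' preictal windows and time already under (false) warning.
#'
#' @param alarms an [generate_alarms()] `alarm_series` (or numeric alarm
#'   times in seconds).
#' @param seizure_onsets_s seizure onsets, seconds from record start.
#' @param sop_min assumed preictal duration (seizure occurrence period),
#'   minutes.
#' @param span evaluation span `c(start_s, end_s)`; only alarms and seizures
#'   inside it are scored.
#' @return object of class `performance`: list with `ss`, `fpr` (per hour),
#'   `n_seizures`, `n_predicted`, `n_true_alarms`, `n_false_alarms`,
#'   `denominator_h`.
#' @export
score_alarms <- function(alarms, seizure_onsets_s, sop_min, span) {
  at <- if (inherits(alarms, "alarm_series")) alarms$alarm_times else alarms
  sop_s <- sop_min * 60
  at <- at[at >= span[1] & at < span[2]]
  sz <- seizure_onsets_s[seizure_onsets_s >= span[1] & seizure_onsets_s < span[2]]

  predicted <- vapply(sz, function(on) any(at >= on - sop_s & at < on), TRUE)
  is_true <- vapply(at, function(t) any(sz > t & sz <= t + sop_s), TRUE)

  blocked <- rbind(
    if (length(sz)) cbind(sz - sop_s, sz),
    if (any(!is_true)) cbind(at[!is_true], at[!is_true] + sop_s)
  )
  denom_h <- (diff(span) - .union_length(blocked, span)) / 3600
  if (denom_h <= 0) stop("false-alarm denominator is not positive")

  structure(list(
    ss = if (length(sz)) unname(mean(predicted)) else NA_real_,
    fpr = unname(sum(!is_true) / denom_h),
    n_seizures = length(sz), n_predicted = unname(sum(predicted)),
    n_true_alarms = unname(sum(is_true)),
    n_false_alarms = unname(sum(!is_true)),
    denominator_h = unname(denom_h)
  ), class = "performance")
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf("<performance> SS = %s (%d/%d), FPR = %.3f/h over %.1f h\n",
              ifelse(is.na(x$ss), "NA", sprintf("%.0f%%", 100 * x$ss)),
              x$n_predicted, x$n_seizures, x$fpr, x$denominator_h))
  invisible(x)
}

#' Exhaustive detector parameter optimization on a training span
#'
#' Grid search over the four coupling band pairs, the 11 phase intervals,
#' the preictal durations (10, 30, 60 min) and an occupancy threshold grid,
#' selecting the configuration whose training performance lies closest to
#' the ideal (SS = 1, FPR = 0) under
#' `d = sqrt((1 - SS)^2 + (FPR / fpr_ref)^2)`. Ties break deterministically:
#' lower FPR, then higher SS, then first in enumeration order (pair,
#' interval, preictal duration, threshold). A configuration raising no
#' alarms scores with SS = 0.
#'
#' @param recording an `eeg_recording` with seizures in the training span.
#' @param train_span `c(start_s, end_s)` from [split_train_test()].
#' @param sop_grid preictal durations in minutes (default `c(10, 30, 60)`).
#' @param thresholds occupancy thresholds (proportions of contacts),
#'   default 5\% to 50\% in 1\% steps.
#' @param q,r Kalman smoothing variances (see [kalman_smooth()]).
#' @param fpr_ref FPR normalization in the distance, false alarms/h
#'   (default 1).
#' @param window_s coupling window, seconds (default 60).
#' @param maps optional precomputed list of [coupling_phase_map()]s named by
#'   pair code, to avoid recomputation.
#' @return list with `config` (fields `pair`, `interval`, `sop_min`,
#'   `threshold`), `train_performance`, `distance`, `maps` (for reuse on the
#'   test span) and `search` (a data frame of every configuration scored).
#' @export
optimize_parameters <- function(recording, train_span,
                                sop_grid = c(10, 30, 60),
                                thresholds = seq(0.05, 0.50, by = 0.01),
                                q = 1e-4, r = 1e-2, fpr_ref = 1,
                                window_s = 60, maps = NULL) {
  pairs <- band_pair_grid(recording$fs)
  intervals <- phase_interval_grid()
  if (is.null(maps)) {
    maps <- coupling_phase_maps(recording, pairs, window_s = window_s)
  }
  onsets <- recording$annotations$onset_s
  if (!any(onsets >= train_span[1] & onsets < train_span[2])) {
    stop("training span contains no seizure")
  }

  rows <- vector("list", 2000)
  nr <- 0
  for (pc in names(pairs)) {
    map <- maps[[pc]]
    for (iv in seq_len(nrow(intervals))) {
      occ <- smooth_occupancy(occupancy(map, intervals[iv, ]), q, r)
      for (sop in sop_grid) {
        for (thr in thresholds) {
          al <- generate_alarms(occ$smoothed, thr, sop * 60, window_s,
                                occ$window_times_s)
          # configs so permissive that warnings blanket the whole span have
          # no time left in which a false alarm could occur; rank them last
          perf <- tryCatch(score_alarms(al, onsets, sop, train_span),
                           error = function(e) list(ss = 0, fpr = Inf))
          ss <- if (is.na(perf$ss)) 0 else perf$ss
          nr <- nr + 1
          rows[[nr]] <- data.frame(pair = pc, interval = iv, sop_min = sop,
                                   threshold = thr, ss = ss, fpr = perf$fpr)
        }
      }
    }
  }
  search <- do.call(rbind, rows[seq_len(nr)])
  search$d <- sqrt((1 - search$ss)^2 + (search$fpr / fpr_ref)^2)
  best <- order(search$d, search$fpr, -search$ss, seq_len(nrow(search)))[1]
  sel <- search[best, ]
  config <- list(pair = pairs[[sel$pair]],
                 interval = intervals[sel$interval, ],
                 sop_min = sel$sop_min, threshold = sel$threshold)
  perf <- evaluate_detector(maps, config, train_span, q = q, r = r)
  list(config = config, train_performance = perf$performance,
       distance = sel$d, maps = maps, search = search)
}

#' Apply a frozen detector configuration to an evaluation span
#'
#' @param maps named list of coupling maps (one per band pair code).
#' @param config detector configuration as returned in
#'   `optimize_parameters()$config`.
#' @param span evaluation span `c(start_s, end_s)`.
#' @param q,r Kalman smoothing variances.
#' @return list with `alarms`, `performance`, `occupancy`.
#' @export
evaluate_detector <- function(maps, config, span, q = 1e-4, r = 1e-2) {
  map <- maps[[config$pair$code]]
  occ <- smooth_occupancy(occupancy(map, config$interval), q, r)
  al <- generate_alarms(occ$smoothed, config$threshold,
                        config$sop_min * 60, map$window_s,
                        occ$window_times_s)
  perf <- score_alarms(al, map$annotations$onset_s, config$sop_min, span)
  list(alarms = al, performance = perf, occupancy = occ)
}

#' Critical sensitivity of the chance-level random predictor
#'
#' A random predictor raises alarms as a Poisson process matched to the
#' observed false prediction rate; the probability that at least one alarm
#' falls in one preictal window of length `sop_min` is
#' `P = 1 - exp(-fpr * sop_h)`. Predicting `k` of `K` seizures by chance
#' then follows a binomial law, and the critical sensitivity is the
#' smallest `k / K` whose binomial upper-tail probability is below `alpha`.
#' A real predictor must exceed this sensitivity (at matched FPR and
#' preictal duration) to beat chance. If even predicting all `K` seizures
#' would not be significant the function returns 1.
#'
#' @param fpr false prediction rate, per hour.
#' @param sop_min preictal duration, minutes.
#' @param K number of seizures in the evaluation span.
#' @param alpha per-patient significance level (default 0.01).
#' @return critical sensitivity `sigma_rand` in `[1/K, 1]`.
#' @export
random_predictor_sensitivity <- function(fpr, sop_min, K, alpha = 0.01) {
  stopifnot(fpr >= 0, K >= 1)
  p1 <- 1 - exp(-fpr * sop_min / 60)
  tail_ge <- stats::pbinom(0:(K - 1), K, p1, lower.tail = FALSE)
  k_star <- which(tail_ge < alpha)
  if (length(k_star) == 0) return(1)
  k_star[1] / K
}

#' Group-level binomial significance
#'
#' Probability of observing at least `n_sig` of `N` patients beating their
#' per-patient random predictor when each does so with probability
#' `alpha_patient` under the null of no true predictive power.
#'
#' @param n_sig patients with individually significant performance.
#' @param N total patients.
#' @param alpha_patient per-patient significance level.
#' @return upper-tail binomial probability.
#' @export
group_significance <- function(n_sig, N, alpha_patient) {
  stopifnot(n_sig >= 0, n_sig <= N)
  if (n_sig == 0) return(1)
  stats::pbinom(n_sig - 1, N, alpha_patient, lower.tail = FALSE)
}

#' Full prospective evaluation of one patient
#'
#' Splits the recording, optimizes the detector on the training span,
#' freezes the selected configuration, evaluates it on the testing span and
#' compares the result with the random predictor at matched FPR and
#' preictal duration.
#'
#' @param recording an `eeg_recording` with at least
#'   `n_train_seizures + 1` annotated seizures.
#' @inheritParams split_train_test
#' @inheritParams optimize_parameters
#' @param alpha per-patient significance level for the random predictor.
#' @return list with `split`, `config`, `train_performance`,
#'   `test_performance`, `sigma_rand`, `significant`, and `maps`.
#' @export
run_prospective <- function(recording, n_train_seizures = 4, min_train_h = 10,
                            sop_grid = c(10, 30, 60),
                            thresholds = seq(0.05, 0.50, by = 0.01),
                            q = 1e-4, r = 1e-2, alpha = 0.01, maps = NULL) {
  split <- split_train_test(recording, n_train_seizures, min_train_h,
                            sop_max_min = max(sop_grid))
  opt <- optimize_parameters(recording, split$train, sop_grid = sop_grid,
                             thresholds = thresholds, q = q, r = r,
                             maps = maps)
  test <- evaluate_detector(opt$maps, opt$config, split$test, q = q, r = r)
  perf <- test$performance
  sigma <- random_predictor_sensitivity(perf$fpr, opt$config$sop_min,
                                        max(perf$n_seizures, 1), alpha)
  list(split = split, config = opt$config,
       train_performance = opt$train_performance,
       test_performance = perf, sigma_rand = sigma,
       significant = !is.na(perf$ss) && perf$ss > sigma,
       maps = opt$maps)
}
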