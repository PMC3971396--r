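#' Burg autoregressive power spectral density
#'
#' Fits an AR model by the Burg method (through [stats::ar()]) and evaluates
#' its one-sided power spectral density on a regular frequency grid over
#' `[0, fs/2]`. The PSD integrates (trapezoidally) to approximately the
#' signal variance. A (near-)constant signal cannot support an AR fit and is
#' returned flagged degenerate with an NA spectrum.
#'
#' @param x signal samples (one window).
#' @param fs sampling rate in Hz.
#' @param order AR model order (default 16, a standard compromise for 5-s
#'   EEG windows).
#' @param n_freq number of frequency points (default 1025, i.e. a
#'   2048-point evaluation grid; 0.125 Hz spacing at 256 Hz, fine enough to
#'   integrate sharp low-frequency AR peaks).
#' @return list with `freq` (Hz), `psd` (power per Hz), `order`,
#'   `degenerate` (logical).
#' @export
burg_psd <- function(x, fs, order = 16, n_freq = 1025) {
  if (length(x) < 2 * order) stop("window too short for AR order ", order)
  nfft <- 2 * (n_freq - 1)
  freq <- (0:(n_freq - 1)) * fs / nfft
  if (stats::var(x) < .Machine$double.eps) {
    return(list(freq = freq, psd = rep(NA_real_, n_freq), order = order,
                degenerate = TRUE))
  }
  fit <- tryCatch(
    stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$var.pred) || fit$var.pred <= 0) {
    return(list(freq = freq, psd = rep(NA_real_, n_freq), order = order,
                degenerate = TRUE))
  }
  a <- stats::fft(c(1, -fit$ar, rep(0, nfft - order - 1)))[1:n_freq]
  psd <- fit$var.pred / fs / Mod(a)^2
  psd[2:(n_freq - 1)] <- 2 * psd[2:(n_freq - 1)]   # one-sided
  list(freq = freq, psd = psd, order = order, degenerate = FALSE)
}

.power_band_defs <- function(fs) {
  top <- min(140, 0.9 * fs / 2)
  list(delta = c(0.1, 4), theta = c(4, 8), gamma = c(30, top),
       total = c(0.1, top))
}

# trapezoidal band integral of a PSD on its grid
.band_integral <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Channel-averaged relative band power over 5-second windows
#'
#' For every consecutive window the Burg PSD of each channel is integrated
#' over the requested band and divided by the power over the whole analyzed
#' range (0.1 Hz to 140 Hz, capped at 90\% of Nyquist); the ratio is then
#' averaged across channels. Degenerate windows (flat signal) are dropped
#' from the channel average; a window degenerate on all channels is NA.
#'
#' @param recording an `eeg_recording` of at least one window.
#' @param band `"delta"` (0.1-4 Hz), `"theta"` (4-8 Hz) or `"gamma"`
#'   (30-140 Hz).
#' @param window_s window length in seconds (default 5).
#' @param order AR order for [burg_psd()].
#' @return object of class `power_series`: list with `values` (per-window
#'   relative power in `[0, 1]`), `band`, `band_hz`, `window_s`,
#'   `window_times_s`.
#' @export
relative_band_power <- function(recording, band = c("delta", "theta", "gamma"),
                                window_s = 5, order = 16) {
  band <- match.arg(band)
  rel <- .relative_power_multi(recording, band, window_s, order)[[band]]
  defs <- .power_band_defs(recording$fs)
  structure(list(values = rel$values, band = band, band_hz = defs[[band]],
                 window_s = window_s, window_times_s = rel$times),
            class = "power_series")
}

# Shared engine: one Burg fit per (channel, window), integrals for all
# requested bands at once. Returns per band a channel-averaged series.
.relative_power_multi <- function(recording, bands, window_s = 5,
                                  order = 16) {
  defs <- .power_band_defs(recording$fs)
  win <- segment_windows(recording, window_s)
  if (nrow(win) == 0) stop("recording shorter than one window")
  nch <- nrow(recording$signals)
  n_win <- nrow(win)
  acc <- lapply(bands, function(b) matrix(NA_real_, nch, n_win))
  names(acc) <- bands
  for (ch in seq_len(nch)) {
    x <- recording$signals[ch, ]
    for (w in seq_len(n_win)) {
      seg <- x[(win$start_sample[w] + 1):win$end_sample[w]]
      sp <- burg_psd(seg, recording$fs, order = order)
      if (sp$degenerate) next
      tot <- .band_integral(sp$freq, sp$psd, defs$total)
      if (tot <= 0) next
      for (b in bands) {
        acc[[b]][ch, w] <- .band_integral(sp$freq, sp$psd, defs[[b]]) / tot
      }
    }
  }
  times <- win$start_sample / recording$fs
  lapply(acc, function(m) {
    v <- colMeans(m, na.rm = TRUE)
    v[colSums(!is.na(m)) == 0] <- NA_real_
    list(values = v, times = times)
  })
}

#' Band-power baseline predictor
#'
#' The comparison predictor: alarms are raised when the raw channel-averaged
#' relative power of one band crosses a threshold (no Kalman smoothing),
#' with the same refractory rule and scoring as the coupling detector.
#'
#' @param recording an `eeg_recording` with seizure annotations.
#' @param band `"delta"`, `"theta"` or `"gamma"`.
#' @param threshold relative-power threshold in `(0, 1)`.
#' @param sop_min preictal duration (and refractory period), minutes.
#' @param span evaluation span `c(start_s, end_s)`; defaults to the whole
#'   record.
#' @param series optional precomputed [relative_band_power()] series.
#' @return list with `alarms`, `performance`, `series`.
#' @export
power_detector <- function(recording, band, threshold, sop_min, span = NULL,
                           series = NULL) {
  if (is.null(series)) series <- relative_band_power(recording, band)
  if (is.null(span)) span <- c(0, recording_duration(recording))
  al <- generate_alarms(series$values, threshold, sop_min * 60,
                        series$window_s, series$window_times_s)
  perf <- score_alarms(al, recording$annotations$onset_s, sop_min, span)
  list(alarms = al, performance = perf, series = series)
}

#' Train and prospectively evaluate the band-power baseline
#'
#' Mirrors the coupling pipeline: for each band the threshold (a grid of
#' training-series quantiles) and preictal duration are optimized in-sample
#' on the training span by the same closest-to-ideal distance, then the
#' frozen configuration is scored on the test span and compared with the
#' random predictor.
#'
#' @param recording an `eeg_recording`.
#' @param split output of [split_train_test()].
#' @param bands bands to evaluate (default all three).
#' @param sop_grid preictal durations in minutes.
#' @param probs quantile grid defining candidate thresholds.
#' @param alpha per-patient significance level.
#' @param fpr_ref FPR normalization of the optimization distance.
#' @return named list (per band) with `config` (`threshold`, `sop_min`),
#'   `train_performance`, `test_performance`, `sigma_rand`, `significant`,
#'   `series`.
#' @export
optimize_power_detector <- function(recording, split,
                                    bands = c("delta", "theta", "gamma"),
                                    sop_grid = c(10, 30, 60),
                                    probs = seq(0.50, 0.99, by = 0.01),
                                    alpha = 0.01, fpr_ref = 1) {
  onsets <- recording$annotations$onset_s
  multi <- .relative_power_multi(recording, bands)
  out <- lapply(bands, function(b) {
    ser <- structure(list(values = multi[[b]]$values, band = b,
                          band_hz = .power_band_defs(recording$fs)[[b]],
                          window_s = 5, window_times_s = multi[[b]]$times),
                     class = "power_series")
    in_train <- ser$window_times_s < split$train[2]
    thr_grid <- unique(stats::quantile(ser$values[in_train],
                                       probs = probs, na.rm = TRUE,
                                       names = FALSE))
    thr_grid <- thr_grid[thr_grid > 0 & thr_grid < 1]
    best <- NULL
    for (sop in sop_grid) {
      for (thr in thr_grid) {
        al <- generate_alarms(ser$values, thr, sop * 60, ser$window_s,
                              ser$window_times_s)
        perf <- tryCatch(score_alarms(al, onsets, sop, split$train),
                         error = function(e) list(ss = 0, fpr = Inf,
                                                  train = NULL))
        ss <- if (is.na(perf$ss)) 0 else perf$ss
        d <- sqrt((1 - ss)^2 + (perf$fpr / fpr_ref)^2)
        if (is.null(best) || d < best$d ||
            (d == best$d && perf$fpr < best$fpr)) {
          best <- list(d = d, thr = thr, sop = sop, fpr = perf$fpr,
                       train = perf)
        }
      }
    }
    det <- power_detector(recording, b, best$thr, best$sop,
                          span = split$test, series = ser)
    perf <- det$performance
    sigma <- random_predictor_sensitivity(perf$fpr, best$sop,
                                          max(perf$n_seizures, 1), alpha)
    list(config = list(threshold = best$thr, sop_min = best$sop),
         train_performance = best$train, test_performance = perf,
         sigma_rand = sigma,
         significant = !is.na(perf$ss) && perf$ss > sigma,
         series = ser)
  })
  names(out) <- bands
  out
}
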