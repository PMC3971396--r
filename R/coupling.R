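#' Frequency band pair for phase-amplitude coupling
#'
#' The coupling analysis pairs the phase of a slow band -- delta (0.5-3 Hz)
#' or theta (3-8 Hz) -- with the amplitude envelope of a gamma band -- low
#' gamma LG (40-70 Hz) or high gamma HG (70-140 Hz, reduced to 70-120 Hz at
#' a 256 Hz sampling rate where 140 Hz would exceed Nyquist headroom).
#'
#' @param low `"delta"` or `"theta"`.
#' @param high `"LG"` or `"HG"`.
#' @param fs sampling rate in Hz (decides the HG upper edge).
#' @return an object of class `band_pair` with fields `low_name`, `low_hz`,
#'   `high_name`, `high_hz` and a short `code` (e.g. `"LD"` for LG/delta).
#' @export
band_pair <- function(low = c("delta", "theta"), high = c("LG", "HG"), fs) {
  low <- match.arg(low)
  high <- match.arg(high)
  low_hz <- switch(low, delta = c(0.5, 3), theta = c(3, 8))
  high_hz <- switch(high, LG = c(40, 70),
                    HG = if (fs == 256) c(70, 120) else c(70, 140))
  if (high_hz[2] >= fs / 2) stop("high band exceeds Nyquist for fs = ", fs)
  stopifnot(low_hz[2] < high_hz[1])
  code <- paste0(substr(high, 1, 1), toupper(substr(low, 1, 1)))
  structure(list(low_name = low, low_hz = low_hz, high_name = high,
                 high_hz = high_hz, code = code),
            class = "band_pair")
}

#' All four coupling band pairs for a sampling rate
#' @param fs sampling rate in Hz.
#' @return named list of [band_pair()] objects (`LD`, `LT`, `HD`, `HT`).
#' @export
band_pair_grid <- function(fs) {
  prs <- list(band_pair("delta", "LG", fs), band_pair("theta", "LG", fs),
              band_pair("delta", "HG", fs), band_pair("theta", "HG", fs))
  names(prs) <- vapply(prs, `[[`, "", "code")
  prs
}

#' Phase-amplitude histogram
#'
#' Bins the instantaneous low-band phase into `n_bins` equal intervals
#' tiling `(-pi, pi]` and averages the concurrent high-band amplitude within
#' each bin. Samples with undefined (NA) phase are excluded; counts sum to
#' the number of binned samples.
#'
#' @param phase radians in `(-pi, pi]`.
#' @param amplitude non-negative envelope values, same length as `phase`.
#' @param n_bins number of phase bins (default 40).
#' @return object of class `pa_histogram`: list with `bin_edges` (length
#'   `n_bins + 1`), `bin_centers`, `mean_amplitude` (NA in empty bins),
#'   `counts`, and `empty` (logical flag per bin).
#' @export
phase_amplitude_histogram <- function(phase, amplitude, n_bins = 40) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude must have equal length")
  }
  keep <- is.finite(phase) & is.finite(amplitude)
  phase <- phase[keep]; amplitude <- amplitude[keep]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(phase, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  if (length(bin) > 0) {
    rs <- rowsum(amplitude, bin)
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  mean_amp <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mean_amplitude = mean_amp, counts = counts,
                 empty = counts == 0),
            class = "pa_histogram")
}

#' Mean coupling phase of a phase-amplitude histogram
#'
#' Summarizes a unimodal amplitude-over-phase distribution by the mean of a
#' Von Mises (circular Gaussian) fit, computed as the amplitude-weighted
#' circular mean of the bin centers (the maximum-likelihood Von Mises mean).
#' Empty bins are excluded. The resultant length of the amplitude-normalized
#' distribution is returned as a concentration index in `[0, 1]`: it is 1
#' when all amplitude sits in one bin and near 0 for a flat distribution,
#' where the mean phase is unreliable.
#'
#' @param hist a [phase_amplitude_histogram()].
#' @return list with `phi_c` (radians in `(-pi, pi]`, NA if undefined) and
#'   `concentration` in `[0, 1]`.
#' @export
mean_coupling_phase <- function(hist) {
  stopifnot(inherits(hist, "pa_histogram"))
  use <- !hist$empty
  if (!any(use)) stop("all histogram bins are empty")
  w <- hist$mean_amplitude[use]
  th <- hist$bin_centers[use]
  sw <- sum(w)
  if (sw <= 0) return(list(phi_c = NA_real_, concentration = 0))
  z <- sum(w * exp(1i * th)) / sw
  list(phi_c = Arg(z), concentration = Mod(z))
}

#' Per-contact mean coupling phase in consecutive windows
#'
#' The central extraction step: for every channel, the raw signal is
#' band-pass filtered (zero-phase Butterworth, order 8 forward-backward) in
#' the slow and gamma bands of `pair` over the full record, instantaneous
#' phase and amplitude are taken from the Hilbert analytic signal, and in
#' each consecutive non-overlapping window the amplitude-over-phase
#' histogram is reduced to a mean coupling phase and concentration.
#'
#' For multi-hour records the filtering + analytic step runs on overlapping
#' spectral chunks with band-limited decimation (an exact reformulation of
#' the same zero-phase response; see the methods vignette); `method =
#' "exact"` forces the plain whole-record path used for short signals.
#' The first and last `edge_trim_s` seconds of the record are excluded from
#' histogramming to avoid filter edge transients.
#'
#' @param recording an `eeg_recording`.
#' @param pair a [band_pair()].
#' @param window_s window length in seconds (default 60).
#' @param n_bins phase bins per histogram (default 40).
#' @param edge_trim_s seconds trimmed at both record edges (default 5).
#' @param method `"auto"`, `"spectral"` or `"exact"`.
#' @return object of class `coupling_map`: `phi_c` and `concentration` are
#'   channels x windows matrices; plus `pair`, `window_s`, `window_times_s`
#'   (window start times, seconds), `channel_labels`, `fs`, `duration_s`,
#'   and the recording's `annotations`.
#' @export
coupling_phase_map <- function(recording, pair, window_s = 60, n_bins = 40,
                               edge_trim_s = 5,
                               method = c("auto", "spectral", "exact")) {
  stopifnot(inherits(pair, "band_pair"))
  maps <- coupling_phase_maps(recording, list(pair), window_s = window_s,
                              n_bins = n_bins, edge_trim_s = edge_trim_s,
                              method = method)
  maps[[1]]
}

#' Coupling maps for several band pairs in one pass
#'
#' Computes [coupling_phase_map()] for each requested band pair while
#' extracting every distinct frequency band of a channel from a single
#' forward Fourier pass, which is considerably faster than mapping the
#' pairs one at a time on multi-hour records.
#'
#' @inheritParams coupling_phase_map
#' @param pairs list of [band_pair()] objects (default all four pairs).
#' @return named list of `coupling_map` objects (by pair code).
#' @export
coupling_phase_maps <- function(recording, pairs = band_pair_grid(recording$fs),
                                window_s = 60, n_bins = 40, edge_trim_s = 5,
                                method = c("auto", "spectral", "exact")) {
  method <- match.arg(method)
  fs <- recording$fs
  n <- ncol(recording$signals)
  if (n / fs < window_s) stop("recording shorter than one window")
  win <- segment_windows(recording, window_s)
  n_win <- nrow(win)
  spw <- round(window_s * fs)
  nch <- nrow(recording$signals)

  # distinct bands across pairs, and each pair's (low, high) band index
  key_of <- function(hz, tp) paste(tp, hz[1], hz[2])
  bands <- list(); band_key <- character(0)
  idx_of <- function(hz, tp) {
    k <- key_of(hz, tp)
    i <- match(k, band_key)
    if (is.na(i)) {
      bands[[length(bands) + 1L]] <<- list(band_hz = hz, type = tp)
      band_key <<- c(band_key, k)
      i <- length(bands)
    }
    i
  }
  pair_idx <- lapply(pairs, function(p) {
    c(low = idx_of(p$low_hz, "phase"), high = idx_of(p$high_hz, "amplitude"))
  })

  plan <- .band_plan(fs, bands)
  use_exact <- method == "exact" || (method == "auto" && n < plan$C)
  d <- plan$d

  # decimated-sample bookkeeping shared by all channels
  n_out <- (n - 1L) %/% d + 1L
  samp0 <- (seq_len(n_out) - 1L) * d           # 0-based original sample
  win_id <- samp0 %/% spw + 1L                 # 1-based window
  t_s <- samp0 / fs
  win_id[t_s < edge_trim_s | t_s >= n / fs - edge_trim_s |
           win_id > n_win] <- 0L
  win_id <- as.integer(win_id)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cosc <- cos(centers); sinc <- sin(centers)

  np <- length(pairs)
  phi <- lapply(seq_len(np), function(i) matrix(NA_real_, nch, n_win))
  conc <- lapply(seq_len(np), function(i) matrix(NA_real_, nch, n_win))

  for (ch in seq_len(nch)) {
    x <- recording$signals[ch, ]
    ser <- if (use_exact) .band_series_exact(x, fs, bands, d)
           else .band_series(x, plan)
    for (ip in seq_len(np)) {
      acc <- .pa_accumulate_cpp(ser[[pair_idx[[ip]]["low"]]],
                                ser[[pair_idx[[ip]]["high"]]],
                                win_id, n_bins, n_win)
      cntm <- matrix(acc$counts, n_bins, n_win)
      meanm <- matrix(acc$sums, n_bins, n_win) / cntm   # NaN in empty bins
      meanm[cntm == 0] <- 0                             # empty bins excluded
      wsum <- colSums(meanm)
      zre <- as.vector(crossprod(meanm, cosc)) / wsum
      zim <- as.vector(crossprod(meanm, sinc)) / wsum
      ok <- is.finite(wsum) & wsum > 0 & colSums(cntm) > 0
      phi[[ip]][ch, ok] <- atan2(zim[ok], zre[ok])
      conc[[ip]][ch, ok] <- sqrt(zre[ok]^2 + zim[ok]^2)
    }
  }

  maps <- lapply(seq_len(np), function(ip) {
    structure(list(phi_c = phi[[ip]], concentration = conc[[ip]],
                   pair = pairs[[ip]], window_s = window_s,
                   window_times_s = win$start_sample / fs,
                   channel_labels = recording$channel_labels, fs = fs,
                   duration_s = n / fs, annotations = recording$annotations),
              class = "coupling_map")
  })
  names(maps) <- vapply(pairs, function(p) p$code, "")
  maps
}

#' @export
print.coupling_map <- function(x, ...) {
  cat(sprintf("<coupling_map> %s: %d channels x %d windows of %g s\n",
              x$pair$code, nrow(x$phi_c), ncol(x$phi_c), x$window_s))
  invisible(x)
}
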