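#' The canonical 11-interval phase grid
#'
#' Eleven equal, non-overlapping intervals of width `2 * pi / 11` tiling
#' `(-pi, pi]`. Intervals are half-open `[lo, hi)`; the last interval is
#' closed at `pi` so the grid partitions the circle exactly.
#'
#' @return data frame with 11 rows and columns `lo`, `hi`, `center`.
#' @export
phase_interval_grid <- function() {
  w <- 2 * pi / 11
  lo <- -pi + (0:10) * w
  data.frame(lo = lo, hi = lo + w, center = lo + w / 2)
}

# membership of phases in [lo, hi), last grid interval closed at pi
.in_interval <- function(phi, interval) {
  hi_closed <- abs(interval$hi - pi) < 1e-9
  phi >= interval$lo & (phi < interval$hi | (hi_closed & phi <= pi))
}

#' Phase-interval occupancy of a contact ensemble
#'
#' For each window, the proportion of contacts whose mean coupling phase
#' falls inside a phase interval. Channels with an undefined phase in a
#' window are excluded from both numerator and denominator; a window where
#' every channel is undefined gets an NA (missing) occupancy.
#'
#' @param map a [coupling_phase_map()].
#' @param interval one row of [phase_interval_grid()] (or any list with
#'   `lo`, `hi` in radians).
#' @return object of class `occupancy_series`: list with `raw` (per-window
#'   proportions), `smoothed` (NULL until [kalman_smooth()] is applied via
#'   [smooth_occupancy()]), `interval`, `window_s`, `window_times_s`.
#' @export
occupancy <- function(map, interval) {
  stopifnot(inherits(map, "coupling_map"))
  member <- .in_interval(map$phi_c, interval)    # NA where phi_c undefined
  raw <- colMeans(member, na.rm = TRUE)
  raw[colSums(!is.na(member)) == 0] <- NA_real_
  structure(list(raw = raw, smoothed = NULL, interval = interval,
                 window_s = map$window_s, window_times_s = map$window_times_s),
            class = "occupancy_series")
}

#' Causal first-order Kalman smoothing of a proportion series
#'
#' One-dimensional random-walk Kalman filter (state = true proportion,
#' observation = raw occupancy) run causally, so no future window influences
#' the estimate. NA observations are treated as missing: the filter
#' propagates its prediction and inflates its variance. The filter is
#' initialized at the first observation with variance `r`.
#'
#' @param x numeric series in `[0, 1]` (NAs allowed as missing windows).
#' @param q process variance per step (default 1e-4).
#' @param r observation variance (default 1e-2).
#' @return smoothed series, same length.
#' @export
kalman_smooth <- function(x, q = 1e-4, r = 1e-2) {
  stopifnot(q > 0, r > 0)
  if (any(is.infinite(x) | is.nan(x))) stop("non-finite values in input series")
  n <- length(x)
  out <- numeric(n)
  est <- NA_real_
  p <- r
  for (i in seq_len(n)) {
    p <- p + q
    z <- x[i]
    if (is.na(est)) {
      est <- z                     # NA until the first observation
      p <- r
    } else if (!is.na(z)) {
      k <- p / (p + r)
      est <- est + k * (z - est)
      p <- (1 - k) * p
    }
    out[i] <- est
  }
  out
}

#' Smooth an occupancy series
#' @param occ an `occupancy_series`.
#' @inheritParams kalman_smooth
#' @return the series with its `smoothed` field filled in.
#' @export
smooth_occupancy <- function(occ, q = 1e-4, r = 1e-2) {
  stopifnot(inherits(occ, "occupancy_series"))
  occ$smoothed <- kalman_smooth(occ$raw, q, r)
  occ
}

#' Threshold alarms with a refractory period
#'
#' Raises an alarm at the start time of every window whose (smoothed)
#' occupancy exceeds the threshold, unless a previous alarm lies within the
#' refractory period. The refractory period equals the assumed preictal
#' duration in the prediction pipeline.
#'
#' @param smoothed numeric series (one value per window).
#' @param threshold proportion in `(0, 1)`.
#' @param refractory_s refractory period in seconds.
#' @param window_s window duration in seconds.
#' @param times_s optional window start times (seconds); defaults to
#'   `0, window_s, 2 * window_s, ...`.
#' @return object of class `alarm_series`: list with `alarm_times` (seconds),
#'   `threshold`, `refractory_s`.
#' @export
generate_alarms <- function(smoothed, threshold, refractory_s, window_s,
                            times_s = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(times_s)) times_s <- (seq_along(smoothed) - 1) * window_s
  cand <- which(!is.na(smoothed) & smoothed > threshold)
  alarms <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (times_s[i] - last >= refractory_s) {
      alarms <- c(alarms, times_s[i])
      last <- times_s[i]
    }
  }
  structure(list(alarm_times = alarms, threshold = threshold,
                 refractory_s = refractory_s),
            class = "alarm_series")
}

#' Contacts implicated in a preictal phase shift
#'
#' A contact is implicated when its per-window incidence inside the phase
#' interval during preictal windows is at least twice its interictal
#' incidence (inclusive boundary); a contact with zero interictal incidence
#' but any preictal incidence is also implicated.
#'
#' @param map a [coupling_phase_map()].
#' @param interval a phase interval (row of [phase_interval_grid()]).
#' @param preictal_windows,interictal_windows 1-based window column indices.
#' @return character vector of implicated channel labels.
#' @export
identify_implicated_contacts <- function(map, interval, preictal_windows,
                                         interictal_windows) {
  stopifnot(inherits(map, "coupling_map"))
  if (length(preictal_windows) == 0 || length(interictal_windows) == 0) {
    stop("both window sets must be non-empty")
  }
  member <- .in_interval(map$phi_c, interval)
  pre <- rowMeans(member[, preictal_windows, drop = FALSE], na.rm = TRUE)
  inter <- rowMeans(member[, interictal_windows, drop = FALSE], na.rm = TRUE)
  imp <- ifelse(inter > 0, pre >= 2 * inter, pre > 0)
  imp[is.na(imp)] <- FALSE
  map$channel_labels[imp]
}
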