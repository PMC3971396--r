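#' Specification of a synthetic coupled-EEG patient
#'
#' Describes a multichannel record in which an amplitude-modulated gamma
#' carrier nests within a narrowband slow oscillation at a programmable
#' per-channel coupling phase. Ahead of each annotated seizure, a fraction
#' of channels shifts its coupling phase to `preictal_phase` for the
#' preictal duration, emulating the ensemble phase reorganization the
#' prediction pipeline is designed to detect.
#'
#' Defaults describe the package's reference test patient: 16 contacts at
#' 256 Hz for 12 hours with 6 seizures spaced more than 1.5 h apart, a
#' stable interictal coupling phase of 0.81 rad, preictal shifts of 60\% of
#' channels towards 0.24 rad during the 60 min before each onset, and
#' modulation depth 0.8.
#'
#' @param n_channels number of contacts.
#' @param fs sampling rate, Hz.
#' @param duration_s record length, seconds.
#' @param slow_band_hz,fast_band_hz slow (phase) and fast (amplitude) bands.
#' @param interictal_phase baseline coupling phase per channel, radians
#'   (recycled across channels).
#' @param preictal_phase coupling phase adopted preictally, radians.
#' @param preictal_fraction fraction of channels that shift preictally.
#' @param modulation_depth envelope modulation depth in `[0, 1]`.
#' @param sop_min preictal duration, minutes.
#' @param seizure_onsets_s seizure onsets, seconds (must leave room for one
#'   preictal window and be spaced > 1.5 h apart when the duration allows).
#' @param slow_amp,fast_amp RMS amplitudes of the slow oscillation and the
#'   gamma carrier, microvolts.
#' @param noise_sd white measurement noise SD, microvolts.
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   recordings.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 16, fs = 256, duration_s = 12 * 3600,
                           slow_band_hz = c(0.5, 3), fast_band_hz = c(40, 70),
                           interictal_phase = 0.81, preictal_phase = 0.24,
                           preictal_fraction = 0.6, modulation_depth = 0.8,
                           sop_min = 60,
                           seizure_onsets_s = c(2.0, 3.7, 5.4, 7.1, 9.1, 10.9) * 3600,
                           slow_amp = 50, fast_amp = 10, noise_sd = 5,
                           seed = 1) {
  stopifnot(modulation_depth >= 0, modulation_depth <= 1,
            preictal_fraction >= 0, preictal_fraction <= 1,
            fs > 0, duration_s > 0, n_channels >= 1)
  if (fast_band_hz[2] >= fs / 2) stop("fast band exceeds Nyquist")
  on <- seizure_onsets_s
  if (length(on) > 0) {
    if (is.unsorted(on, strictly = TRUE)) stop("seizure onsets must increase")
    if (on[1] < sop_min * 60) {
      stop("first seizure onset must leave room for one preictal window")
    }
    if (on[length(on)] > duration_s) stop("seizure onset beyond record end")
    if (length(on) > 1 && duration_s > length(on) * 5400 &&
        any(diff(on) <= 5400)) {
      stop("seizure onsets must be separated by more than 1.5 hours")
    }
  }
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 slow_band_hz = slow_band_hz, fast_band_hz = fast_band_hz,
                 interictal_phase = rep_len(interictal_phase, n_channels),
                 preictal_phase = preictal_phase,
                 preictal_fraction = preictal_fraction,
                 modulation_depth = modulation_depth, sop_min = sop_min,
                 seizure_onsets_s = on, slow_amp = slow_amp,
                 fast_amp = fast_amp, noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

# one channel's worth of coupled signal given the shared slow oscillation
# (unit RMS) and its instantaneous phase; draws the carrier and noise from
# the current RNG state. phi0 is the baseline coupling phase; pre_idx lists
# sample index ranges that couple at phi_pre instead.
.coupled_channel <- function(spec, n, slow, cos_ph, sin_ph, phi0,
                             pre_idx = NULL, phi_pre = NULL) {
  carrier <- bandpass_filter(stats::rnorm(n), spec$fast_band_hz, spec$fs)
  carrier <- carrier / stats::sd(carrier)
  env <- 1 + spec$modulation_depth *
    (cos_ph * cos(phi0) + sin_ph * sin(phi0))
  if (!is.null(pre_idx)) {
    for (idx in pre_idx) {
      env[idx] <- 1 + spec$modulation_depth *
        (cos_ph[idx] * cos(phi_pre) + sin_ph[idx] * sin(phi_pre))
    }
  }
  env[env < 0] <- 0
  spec$slow_amp * slow + spec$fast_amp * carrier * env +
    stats::rnorm(n, sd = spec$noise_sd)
}

#' Generate one channel of phase-coupled signal
#'
#' Standalone single-channel generator: a narrowband stochastic slow
#' oscillation plus a gamma carrier whose envelope is
#' `1 + depth * cos(phase_slow - coupling_phase)` (floored at 0), plus white
#' noise. Deterministic given `spec$seed` and the channel index.
#'
#' @param spec a [synthetic_spec()].
#' @param channel channel index (used only to decorrelate the RNG stream).
#' @param window time span `c(t0_s, t1_s)` to generate (default the whole
#'   record).
#' @param coupling_phase imposed coupling phase, radians.
#' @return numeric vector of samples (microvolts).
#' @export
generate_coupled_signal <- function(spec, channel = 1,
                                    window = c(0, spec$duration_s),
                                    coupling_phase = 0) {
  n <- round((window[2] - window[1]) * spec$fs)
  if (n < spec$fs) stop("window too short")
  set.seed(spec$seed + 7919L * as.integer(channel))
  slow <- bandpass_filter(stats::rnorm(n), spec$slow_band_hz, spec$fs)
  slow <- slow / stats::sd(slow)
  ph <- analytic_signal(slow)$phase
  .coupled_channel(spec, n, slow, cos(ph), sin(ph), coupling_phase)
}

#' Generate a synthetic patient with preictal coupling-phase shifts
#'
#' The slow oscillation is one coherent field shared by every contact
#' (slow cortical waves are spatially widespread); each contact carries an
#' independent gamma carrier and measurement noise. Interictally a channel
#' couples at its `interictal_phase`; during the `sop_min` minutes before
#' each annotated onset, the randomly chosen `preictal_fraction` of
#' channels couples at `preictal_phase` instead.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_patient` with `recording` (an
#'   `eeg_recording`) and `manifest` (every planted parameter plus the
#'   shifted channel set).
#' @export
generate_patient <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  set.seed(spec$seed)

  fld <- .analytic_field(stats::rnorm(n), fs, spec$slow_band_hz)
  s_sd <- stats::sd(fld$signal)
  slow <- fld$signal / s_sd
  cos_ph <- fld$cos_ph; sin_ph <- fld$sin_ph

  n_shift <- round(spec$preictal_fraction * spec$n_channels)
  shifted <- sort(sample(spec$n_channels, n_shift))

  # preictal sample ranges
  sop_s <- spec$sop_min * 60
  pre_idx <- lapply(spec$seizure_onsets_s, function(on) {
    i0 <- max(1L, floor((on - sop_s) * fs) + 1L)
    i1 <- min(n, ceiling(on * fs))
    i0:i1
  })

  sig <- matrix(0, spec$n_channels, n)
  base <- spec$slow_amp * slow
  pre_start <- vapply(pre_idx, min, 0L)
  pre_end <- vapply(pre_idx, max, 0L)
  p1 <- spec$preictal_phase
  for (ch in seq_len(spec$n_channels)) {
    carrier <- bandpass_filter(stats::rnorm(n), spec$fast_band_hz, fs)
    shift_here <- ch %in% shifted && length(pre_idx) > 0
    phi0 <- spec$interictal_phase[ch]
    .compose_channel_cpp(
      sig, ch, base, cos_ph, sin_ph, carrier, 1 / stats::sd(carrier),
      spec$noise_sd, spec$modulation_depth, spec$fast_amp,
      cos(phi0), sin(phi0),
      if (shift_here) pre_start else integer(0),
      if (shift_here) pre_end else integer(0),
      cos(p1), sin(p1)
    )
  }

  ann <- data.frame(onset_s = spec$seizure_onsets_s,
                    label = rep("clinical seizure",
                                length(spec$seizure_onsets_s)))
  rec <- recording(sig, fs, channel_labels = sprintf("SYN%02d",
                                                     seq_len(spec$n_channels)),
                   annotations = ann)
  manifest <- c(unclass(spec),
                list(shifted_channels = rec$channel_labels[shifted]))
  structure(list(recording = rec, manifest = manifest),
            class = "synthetic_patient")
}
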