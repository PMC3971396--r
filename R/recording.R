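#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its
#' sampling rate, absolute start time, channel labels and seizure-onset
#' annotations. Sampling rates 256, 400, 512 and 1024 Hz are the ones
#' produced by common clinical acquisition systems and are accepted
#' silently; any other positive rate is accepted with a warning.
#'
#' @param signals numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param start_time absolute start timestamp in seconds (POSIX epoch).
#' @param channel_labels character vector, one label per channel.
#' @param annotations data frame with columns `onset_s` (seconds from
#'   record start, strictly increasing, within the record) and `label`.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(signals, fs, start_time = 0,
                      channel_labels = NULL, annotations = NULL) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) {
    stop("fs must be a single positive number")
  }
  if (!fs %in% c(256, 400, 512, 1024)) {
    warning("unusual sampling rate ", fs, " Hz")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(signals)))
  }
  stopifnot(length(channel_labels) == nrow(signals))
  if (is.null(annotations)) {
    annotations <- data.frame(onset_s = numeric(0), label = character(0))
  }
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("onset_s", "label") %in% names(annotations)))
  dur <- ncol(signals) / fs
  if (nrow(annotations) > 0) {
    if (any(diff(annotations$onset_s) <= 0)) {
      stop("annotation onsets must be strictly increasing")
    }
    if (any(annotations$onset_s < 0 | annotations$onset_s > dur)) {
      stop("annotation onset outside the record duration")
    }
  }
  structure(
    list(signals = signals, fs = fs, start_time = start_time,
         channel_labels = channel_labels, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min), %d seizure(s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs / 60, nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `eeg_recording`.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signals) / recording$fs
}

#' Consecutive non-overlapping analysis windows
#'
#' Tiles a recording with half-open, 0-based sample ranges
#' `[start_sample, end_sample)` of equal duration. A trailing partial window
#' is discarded so every window carries the same number of samples.
#'
#' @param recording an `eeg_recording`.
#' @param window_s window length in seconds (default 60).
#' @return data frame with columns `window_index` (0-based), `start_sample`,
#'   `end_sample`; zero rows if the recording is shorter than one window.
#' @export
segment_windows <- function(recording, window_s = 60) {
  stopifnot(window_s > 0)
  spw <- round(window_s * recording$fs)
  k <- ncol(recording$signals) %/% spw
  if (k == 0) {
    return(data.frame(window_index = integer(0), start_sample = integer(0),
                      end_sample = integer(0)))
  }
  i <- 0:(k - 1)
  data.frame(window_index = i, start_sample = i * spw,
             end_sample = (i + 1) * spw)
}

.pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = -width)
}

#' Write a recording as EDF plus a CSV annotation sidecar
#'
#' Emits a standard European Data Format file (16-bit samples, 1-second data
#' records, per-channel symmetric physical scaling) and a sidecar CSV with
#' columns `onset_s,label` holding the seizure annotations. The recording
#' duration must be a whole number of seconds.
#'
#' @param recording an `eeg_recording` with finite sample values.
#' @param path output EDF file path.
#' @param annotation_path sidecar CSV path; default `<path>.annotations.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            annotation_path = paste0(path, ".annotations.csv")) {
  sig <- recording$signals
  if (!all(is.finite(sig))) stop("signals contain non-finite values")
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  nch <- nrow(sig)
  n_rec <- ncol(sig) %/% fs
  if (n_rec * fs != ncol(sig)) {
    stop("EDF export requires a whole number of seconds of data")
  }

  pmax_ <- apply(abs(sig), 1, max)
  pmax_[pmax_ == 0] <- 1
  # symmetric digital range so that 0 uV is represented exactly
  dmin <- -32767; dmax <- 32767
  scale <- (dmax - dmin) / (2 * pmax_)
  dig <- round((sig + pmax_) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)

  t0 <- as.POSIXct(recording$start_time, origin = "1970-01-01", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_ascii("0", 8),
    .pad_ascii("X X X X", 80),
    .pad_ascii("Startdate X X X X", 80),
    .pad_ascii(format(t0, "%d.%m.%y"), 8),
    .pad_ascii(format(t0, "%H.%M.%S"), 8),
    .pad_ascii(256 * (1 + nch), 8),
    .pad_ascii("", 44),
    .pad_ascii(n_rec, 8),
    .pad_ascii("1", 8),
    .pad_ascii(nch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    paste0(vapply(recording$channel_labels, .pad_ascii, "", width = 16),
           collapse = ""),
    paste0(rep(.pad_ascii("", 80), nch), collapse = ""),
    paste0(rep(.pad_ascii("uV", 8), nch), collapse = ""),
    paste0(vapply(-pmax_, function(v) .pad_ascii(signif(v, 7), 8), ""),
           collapse = ""),
    paste0(vapply(pmax_, function(v) .pad_ascii(signif(v, 7), 8), ""),
           collapse = ""),
    paste0(rep(.pad_ascii(dmin, 8), nch), collapse = ""),
    paste0(rep(.pad_ascii(dmax, 8), nch), collapse = ""),
    paste0(rep(.pad_ascii("", 80), nch), collapse = ""),
    paste0(rep(.pad_ascii(fs, 8), nch), collapse = ""),
    paste0(rep(.pad_ascii("", 32), nch), collapse = "")
  )
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)

  arr <- array(as.integer(dig), dim = c(nch, fs, n_rec))
  writeBin(as.integer(aperm(arr, c(2, 1, 3))), con, size = 2,
           endian = "little")

  utils::write.csv(recording$annotations, annotation_path, row.names = FALSE)
  invisible(path)
}

#' Read an EDF recording and its CSV annotation sidecar
#'
#' Reads an EDF/EDF+ file whose channels share one sampling rate, restoring
#' physical units from the per-channel scaling, plus seizure annotations
#' from a `onset_s,label` CSV sidecar if one is given and exists.
#' Annotations outside the record duration are a validation error.
#'
#' @param path EDF file path.
#' @param annotation_path optional sidecar CSV path.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, annotation_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    v <- readChar(con, w, useBytes = TRUE)
    if (length(v) == 0 || nchar(v) < w) stop("unreadable EDF file: truncated header")
    trimws(v)
  }
  version <- rd(8)
  if (version != "0") stop("unreadable EDF file: bad version field")
  rd(80); rd(80)
  date_s <- rd(8); time_s <- rd(8)
  rd(8); rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  nch <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(n_rec, rec_dur, nch)) || nch < 1) {
    stop("unreadable EDF file: malformed header")
  }
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("EDF files with mixed per-channel sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * nch * spr[1], size = 2,
                 endian = "little")
  if (length(raw) < n_rec * nch * spr[1]) stop("unreadable EDF file: truncated data")
  arr <- array(raw, dim = c(spr[1], nch, n_rec))
  dig <- matrix(aperm(arr, c(2, 1, 3)), nrow = nch)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- (dig - dmin) * scale + pmin_

  dt <- strptime(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  start_time <- if (is.na(dt)) 0 else as.numeric(dt)

  ann <- NULL
  if (!is.null(annotation_path) && file.exists(annotation_path)) {
    ann <- utils::read.csv(annotation_path,
                           colClasses = c(onset_s = "numeric", label = "character"))
  }
  recording(sig, fs, start_time = start_time, channel_labels = labels,
            annotations = ann)
}

#' EDF amplitude quantization step of a recording
#'
#' The physical value represented by one digital unit when `recording` is
#' written with [write_recording()] (symmetric per-channel scaling over
#' 16-bit integers). Useful as a round-trip tolerance.
#'
#' @param recording an `eeg_recording`.
#' @return numeric vector, one step per channel (microvolts).
#' @export
edf_quantization_step <- function(recording) {
  pmax_ <- apply(abs(recording$signals), 1, max)
  pmax_[pmax_ == 0] <- 1
  2 * pmax_ / 65534
}
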