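# Internal chunked spectral machinery for long records.
#
# The pipeline needs, per channel, the instantaneous phase of one or two slow
# bands and the amplitude envelope of one or two gamma bands over multi-hour
# signals. Doing this with a single whole-record FFT is slow and memory
# hungry, so the record is processed in overlapping chunks: each chunk is
# Fourier transformed once, multiplied by the squared-magnitude Butterworth
# response of each band (the exact zero-phase forward-backward response)
# together with the analytic-signal mask, and inverse transformed on a
# reduced set of bins, yielding the band-limited analytic signal decimated
# by a power of two. Decimation of a band-limited analytic signal is exact
# sample picking, so phases and envelopes are unaffected. Chunk seams use
# generous overlap (an eighth of the chunk on each side) and odd reflection
# at the record edges.

.chunk_len <- function(fs) {
  2L^max(12L, round(log2(64 * fs)))
}

# odd-reflected value lookup outside [1, n]
.reflect_idx_values <- function(x, idx) {
  n <- length(x)
  out <- numeric(length(idx))
  inside <- idx >= 1 & idx <= n
  out[inside] <- x[idx[inside]]
  lo <- idx < 1
  if (any(lo)) out[lo] <- 2 * x[1] - x[2 - idx[lo]]
  hi <- idx > n
  if (any(hi)) out[hi] <- 2 * x[n] - x[2 * n - idx[hi]]
  out
}

# Precompute per-band chunk masks. bands: list of list(band_hz, type) with
# type "phase", "amplitude" or "analytic" (complex output, forces d = 1).
# The mask support keeps bins down to -80 dB of the squared response; the
# energy outside is irrelevant to phase/envelope estimates but keeping the
# support tight allows deeper decimation.
.band_plan <- function(fs, bands, order = 8, d = NULL) {
  C <- .chunk_len(fs)
  P <- C %/% 8L
  H <- C - 2L * P
  f <- (0:(C %/% 2L)) * fs / C          # positive bins 0..Nyquist
  plan_bands <- lapply(bands, function(b) {
    sos <- butter_sos(order, b$band_hz, fs)
    g2 <- Mod(sos_response(sos, f, fs))^2
    m <- 2 * g2                         # analytic doubling for 0 < f < Nyq
    m[1] <- 0
    m[length(m)] <- 0
    ks <- which(m > max(m) * 1e-8)
    list(band_hz = b$band_hz, type = b$type, ks = ks, mk = m[ks])
  })
  if (is.null(d)) {
    if (any(vapply(plan_bands, function(b) b$type == "analytic", TRUE))) {
      d <- 1L
    } else {
      # decimated rate covers the widest nominal band with 25% headroom;
      # filter skirts below that headroom are trimmed before folding
      max_bw <- max(vapply(plan_bands, function(b) diff(b$band_hz), 0))
      d <- 2L^floor(log2(fs / (1.25 * max_bw)))
      d <- max(1L, min(d, P))           # d must divide P (both powers of 2)
    }
  }
  Cd <- C %/% d
  plan_bands <- lapply(plan_bands, function(b) {
    if (diff(range(b$ks)) + 1L > Cd) {
      ctr <- round(mean(b$band_hz) / fs * C) + 1L
      k0 <- max(1L, min(ctr - Cd %/% 2L, max(b$ks) - Cd + 1L))
      keep <- b$ks >= k0 & b$ks <= k0 + Cd - 1L
      b$ks <- b$ks[keep]; b$mk <- b$mk[keep]
    }
    b
  })
  list(C = C, P = P, H = H, d = d, fs = fs, fs_dec = fs / d,
       bands = plan_bands)
}

# Extract all planned band series from one channel. Returns a list of
# vectors (phase in radians, amplitude, or the complex analytic signal),
# one per band, sampled at fs / d. Output length floor((n - 1) / d) + 1.
.band_series <- function(x, plan) {
  n <- length(x)
  C <- plan$C; P <- plan$P; H <- plan$H; d <- plan$d
  n_out <- (n - 1L) %/% d + 1L
  nb <- length(plan$bands)
  types <- vapply(plan$bands, `[[`, "", "type")
  out <- lapply(types, function(tp) {
    if (tp == "analytic") complex(n_out) else numeric(n_out)
  })
  Cd <- C %/% d
  idx_fold <- lapply(plan$bands, function(b) ((b$ks - 1L) %% Cd) + 1L)
  int_lo <- P %/% d + 1L
  n_chunks <- ceiling(n / H)
  for (j in seq_len(n_chunks)) {
    o1 <- 1L + (j - 1L) * H
    i0 <- o1 - P
    seg <- if (i0 >= 1L && i0 + C - 1L <= n) x[i0:(i0 + C - 1L)]
           else .reflect_idx_values(x, i0:(i0 + C - 1L))
    Z <- stats::fft(seg)
    # global decimated output indices covered by this chunk interior
    m1 <- (o1 - 1L) %/% d + 1L
    m2 <- min(m1 + H %/% d - 1L, n_out)
    if (m2 < m1) break
    sel <- int_lo:(int_lo + (m2 - m1))
    for (i in seq_len(nb)) {
      b <- plan$bands[[i]]
      spec <- complex(Cd)
      spec[idx_fold[[i]]] <- Z[b$ks] * b$mk
      zd <- stats::fft(spec, inverse = TRUE) / C
      out[[i]][m1:m2] <- switch(b$type,
                                phase = Arg(zd[sel]),
                                amplitude = Mod(zd[sel]),
                                analytic = zd[sel])
    }
  }
  out
}

# Exact (whole-signal) fallback for short records: time-domain zero-phase
# SOS filtering plus a single-FFT analytic signal, then plain decimation.
.band_series_exact <- function(x, fs, bands, d, order = 8) {
  pick <- seq(1L, length(x), by = d)
  lapply(bands, function(b) {
    flt <- bandpass_filter(x, b$band_hz, fs, order = order)
    a <- analytic_signal(flt)
    switch(b$type,
           phase = a$phase[pick],
           amplitude = a$amplitude[pick],
           analytic = {
             im <- a$amplitude * sin(a$phase)
             im[is.na(im)] <- 0
             complex(real = flt[pick], imaginary = im[pick])
           })
  })
}

# Band-limited analytic field of one signal at full rate (d = 1); used by
# the synthetic generator for the shared slow oscillation.
.analytic_field <- function(x, fs, band_hz) {
  bands <- list(list(band_hz = band_hz, type = "analytic"))
  plan <- .band_plan(fs, bands, d = 1L)
  z <- if (length(x) < plan$C) {
    .band_series_exact(x, fs, bands, 1L)[[1]]
  } else {
    .band_series(x, plan)[[1]]
  }
  amp <- Mod(z)
  amp[amp == 0] <- 1
  list(signal = Re(z), cos_ph = Re(z) / amp, sin_ph = Im(z) / amp)
}
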