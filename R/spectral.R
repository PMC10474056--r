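#' Analytic signal via the frequency domain
#'
#' Zero the negative-frequency half of the spectrum and double the positive
#' half; the magnitude of the result is the amplitude envelope of `x`.
#'
#' @param x real numeric vector
#' @return complex vector, same length
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# time SD of the complex Morlet daughter wavelet at frequency f:
# mother exp(2*pi*1i*fc*t - t^2/fb) has sigma_t = sqrt(fb/2); the daughter
# at scale a = fc/f stretches it by a
cmw_sigma_t <- function(f, center_freq, bandwidth) {
  (center_freq / f) * sqrt(bandwidth / 2)
}

#' Complex Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with the complex Morlet mother
#' `psi(t) = exp(2 pi i fc t - t^2 / fb)` (`fc` = center frequency, `fb` =
#' bandwidth coefficient, both 3 Hz by default: a balanced time-bandwidth
#' compromise for whisker vibration traces). Scales are chosen so the
#' analysis frequencies cover `[f_min, f_max]` in `n_freq` log-spaced steps.
#' Daughters are L1-normalized, so a unit-amplitude tone at any frequency
#' produces a ridge of magnitude 1/2 exactly at that frequency, and ridge
#' decay rates equal amplitude decay rates.
#'
#' The transform is evaluated on a zero-padded domain (`pad` seconds each
#' side, trimmed afterwards) to push wavelet boundary artifacts outside the
#' region of interest; the remaining cone-of-influence margin (e-folding
#' time of the wavelet envelope, per frequency) is reported in `coi`.
#'
#' @param trace a [voltage_trace()] (the offset is removed before analysis)
#' @param f_min,f_max analysis band \[Hz\]; `f_max` defaults to the smaller
#'   of 10 kHz and 0.45 of the sampling rate
#' @param n_freq number of log-spaced frequency steps
#' @param center_freq,bandwidth Morlet parameters `fc`, `fb` \[Hz\]
#' @param pad zero-padding duration on each side \[s\]
#' @return object of class `cmw_spectrogram`: list with `times` \[s\],
#'   `freqs` \[Hz\], `coefs` (complex matrix `n_freq x n_times`), `coi`
#'   \[s\] per frequency, and the parameters
#' @export
cmw_spectrogram <- function(trace, f_min = 2,
                            f_max = min(10000, 0.45 * trace$sample_rate),
                            n_freq = 5000, center_freq = 3, bandwidth = 3,
                            pad = 0.1) {
  stopifnot(inherits(trace, "voltage_trace"), f_min > 0, f_max > f_min,
            n_freq >= 2)
  fs <- trace$sample_rate
  x <- offset_correct(trace)
  n <- length(x)
  npad <- round(pad * fs)
  sig_max <- cmw_sigma_t(f_min, center_freq, bandwidth)
  if ((n + 2 * npad) / fs < 2 * sig_max)
    stop(sprintf(paste0("trace too short for f_min = %g Hz: padded duration ",
                        "%.3g s < 2 wavelet SD %.3g s"),
                 f_min, (n + 2 * npad) / fs, 2 * sig_max))
  ntot <- stats::nextn(n + 2 * npad, c(2, 3, 5))
  xp <- c(numeric(npad), x, numeric(ntot - n - npad))
  X <- stats::fft(xp)
  nu <- c(0:(ntot %/% 2), -((ntot - ntot %/% 2 - 1):1)) * fs / ntot
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freq))
  W <- matrix(0i, n_freq, n)
  keep <- npad + seq_len(n)
  for (k in seq_len(n_freq)) {
    a <- center_freq / freqs[k]
    # FT of exp(2*pi*1i*fc*t - t^2/fb) is sqrt(pi*fb) exp(-pi^2 fb (nu-fc)^2);
    # L1 normalization drops the constant
    psi_hat <- exp(-pi^2 * bandwidth * (a * nu - center_freq)^2)
    row <- stats::fft(X * psi_hat, inverse = TRUE) / ntot
    W[k, ] <- row[keep]
  }
  out <- list(times = trace$t0 + (seq_len(n) - 1L) / fs, freqs = freqs,
              coefs = W,
              coi = sqrt(2) * cmw_sigma_t(freqs, center_freq, bandwidth),
              center_freq = center_freq, bandwidth = bandwidth,
              sample_rate = fs, pad = pad)
  class(out) <- "cmw_spectrogram"
  out
}

#' @export
print.cmw_spectrogram <- function(x, ...) {
  cat(sprintf(
    "cmw_spectrogram: %d freqs [%.3g, %.3g] Hz x %d times [%.4g, %.4g] s (fc = %g, fb = %g)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times), x$center_freq, x$bandwidth))
  invisible(x)
}

#' Magnitude slice of a spectrogram at a fixed time
#'
#' @param spect a [cmw_spectrogram()]
#' @param time time \[s\] (nearest column is used)
#' @return data.frame with `freq` \[Hz\] and `mag`
#' @export
spectrogram_slice <- function(spect, time) {
  k <- which.min(abs(spect$times - time))
  data.frame(freq = spect$freqs, mag = abs(spect$coefs[, k]))
}

#' Partition a spectrum slice into per-mode filter bands
#'
#' Detects modal peaks in a magnitude-versus-frequency slice and assigns
#' each a passband bounded by the deepest amplitude minimum between it and
#' its neighboring peaks (the minima between well-separated resonances are
#' typically tens of dB below the peaks, so hard band edges there split
#' the modes cleanly); the outermost edges extend to the guard margins of
#' the analyzed range. Peaks must rise `threshold_db` above the robust
#' noise floor (lower-half median of the slice in dB, with MAD-based
#' spread); for a single detected peak the band spans the full analyzed
#' range up to the guard margins.
#'
#' @param slice data.frame with columns `freq` and `mag` (e.g. from
#'   [spectrogram_slice()])
#' @param threshold_db required peak elevation above the noise floor \[dB\]
#' @param min_contrast_db required prominence of a peak over the higher of
#'   its flanking minima \[dB\]; rejects the shallow bumps that magnitude
#'   noise produces while keeping real modal peaks (tens of dB contrast)
#' @param guard fraction of the frequency range kept as guard margin at
#'   both ends when no bounding minimum exists
#' @return object of class `band_filter_bank`: data.frame with `j`,
#'   `f_lo`, `f_center`, `f_hi` \[Hz\], `peak_mag`, `contrast_db` (peak over
#'   the deeper adjacent minimum); empty (with a warning) if no peak
#'   clears the threshold
#' @export
band_partition <- function(slice, threshold_db = 10, min_contrast_db = 6,
                           guard = 0.02) {
  freq <- slice$freq; mag <- slice$mag
  stopifnot(length(freq) > 4, all(diff(freq) > 0))
  db <- 20 * log10(pmax(mag, .Machine$double.xmin))
  # robust floor from the lower half of the slice (modal peaks and their
  # skirts inflate whole-slice location estimates), plus its MAD spread
  lower <- db[db <= stats::median(db)]
  floor_db <- stats::median(lower) + stats::mad(lower, center = stats::median(lower))
  n <- length(db)
  is_max <- c(FALSE, db[2:(n - 1)] > db[1:(n - 2)] &
                db[2:(n - 1)] >= db[3:n], FALSE)
  peaks <- which(is_max & db > floor_db + threshold_db)
  empty <- data.frame(j = integer(), f_lo = numeric(), f_center = numeric(),
                      f_hi = numeric(), peak_mag = numeric(),
                      contrast_db = numeric())
  class(empty) <- c("band_filter_bank", "data.frame")
  if (!length(peaks)) {
    warning("no modal peaks above the detection threshold")
    return(empty)
  }
  # merge plateau-adjacent detections, tie-break toward lower frequency
  keep <- peaks[c(TRUE, diff(peaks) > 2)]
  # band edges: the deepest minimum between adjacent detected peaks; the
  # outermost edges extend to the guard margins of the analyzed range
  lo_i <- hi_i <- integer(length(keep))
  lo_i[1] <- max(1L, round(guard * n))
  hi_i[length(keep)] <- min(n, round((1 - guard) * n))
  if (length(keep) > 1) {
    for (k in seq_len(length(keep) - 1)) {
      between <- (keep[k] + 1):(keep[k + 1] - 1)
      cut <- between[which.min(db[between])]
      hi_i[k] <- cut
      lo_i[k + 1] <- cut
    }
  }
  bank <- data.frame(j = seq_along(keep), f_lo = freq[lo_i],
                     f_center = freq[keep], f_hi = freq[hi_i],
                     peak_mag = mag[keep],
                     contrast_db = db[keep] - pmax(db[lo_i], db[hi_i]))
  bank <- bank[bank$contrast_db >= min_contrast_db, , drop = FALSE]
  if (!nrow(bank)) {
    warning("no modal peaks above the detection threshold")
    return(empty)
  }
  bank$j <- seq_len(nrow(bank))
  rownames(bank) <- NULL
  class(bank) <- c("band_filter_bank", "data.frame")
  bank
}

#' Filter bank from known mode frequencies
#'
#' Builds a [band_partition()]-style filter bank directly from a set of
#' modal center frequencies, with band edges at the geometric midpoints
#' between neighbors (and the same ratio extrapolated at the ends, capped
#' to `f_range`). This is the band table used for texture and grating
#' analysis, where the bands are established once from a pole slip-off
#' recording of the same whisker and then applied to transient events; a
#' single event's cross-section does not show every mode at once.
#'
#' @param modes a [solve_eigenmodes()] result or numeric mode frequencies
#'   \[Hz\]
#' @param f_range overall analysis range `c(lo, hi)` \[Hz\]
#' @return a `band_filter_bank` data.frame (`j`, `f_lo`, `f_center`,
#'   `f_hi`, `peak_mag` = NA, `contrast_db` = NA)
#' @export
mode_band_bank <- function(modes, f_range = NULL) {
  f <- sort(mode_freqs(modes))
  stopifnot(length(f) >= 1, all(f > 0))
  if (length(f) == 1) {
    mid <- c(f / 2, f * 2)
  } else {
    inner <- sqrt(f[-1] * f[-length(f)])
    r_lo <- f[1] / (inner[1] / f[1])
    r_hi <- f[length(f)] * (f[length(f)] / inner[length(inner)])
    mid <- c(r_lo, inner, r_hi)
  }
  if (!is.null(f_range)) {
    mid[1] <- max(mid[1], f_range[1])
    mid[length(mid)] <- min(mid[length(mid)], f_range[2])
  }
  bank <- data.frame(j = seq_along(f), f_lo = mid[-length(mid)],
                     f_center = f, f_hi = mid[-1],
                     peak_mag = NA_real_, contrast_db = NA_real_)
  class(bank) <- c("band_filter_bank", "data.frame")
  bank
}

#' FFT bandpass filter
#'
#' Zero-phase frequency-domain mask filtering of the offset-corrected
#' trace: Fourier coefficients outside `[f_lo, f_hi]` are zeroed (hard
#' edges by default; `taper_frac > 0` applies a raised-cosine transition of
#' that fractional width to suppress ringing).
#'
#' @param trace a [voltage_trace()]
#' @param band numeric `c(f_lo, f_hi)` \[Hz\] or one row of a
#'   [band_partition()] result
#' @param taper_frac raised-cosine transition width as a fraction of the
#'   band edges (0 = hard mask)
#' @return a [voltage_trace()] with the filtered, offset-free signal
#' @export
bandpass_mode <- function(trace, band, taper_frac = 0) {
  if (is.data.frame(band)) band <- c(band$f_lo[1], band$f_hi[1])
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  fs <- trace$sample_rate
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  x <- offset_correct(trace)
  n <- length(x)
  X <- stats::fft(x)
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1))) * fs / n
  if (taper_frac <= 0) {
    mask <- as.numeric(f >= band[1] & f <= band[2])
  } else {
    w <- taper_frac * c(band[1], band[2])
    up <- ramp01((f - (band[1] - w[1])) / max(w[1], 1e-12))
    dn <- ramp01(((band[2] + w[2]) - f) / max(w[2], 1e-12))
    mask <- pmin(up, dn)
  }
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  voltage_trace(y, sample_rate = fs, V_off = 0, t0 = trace$t0,
                units = trace$units, gain_label = sprintf(
                  "bandpass %.4g-%.4g Hz", band[1], band[2]))
}

ramp01 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  (1 - cos(pi * x)) / 2
}

#' Mode power envelope
#'
#' Power of a bandpass-filtered, offset-corrected mode trace: the squared
#' magnitude of its analytic signal. For a tone of amplitude `A` the result
#' is `A^2`; for a damped sinusoid with amplitude decay rate `1/tau_a` the
#' envelope decays at `2/tau_a`. The analytic-signal operator avoids the
#' ripple a rectify-and-smooth envelope would superimpose on the decay.
#'
#' @param filtered a [voltage_trace()] as returned by [bandpass_mode()]
#' @return a [voltage_trace()] in `"V^2"`-style squared units
#' @export
mode_power_envelope <- function(filtered) {
  env2 <- Mod(analytic_signal(offset_correct(filtered)))^2
  voltage_trace(env2, sample_rate = filtered$sample_rate, V_off = 0,
                t0 = filtered$t0, units = paste0("(", filtered$units, ")^2"),
                gain_label = "power envelope")
}

#' Per-mode power traces for a whole filter bank
#'
#' Convenience wrapper: [bandpass_mode()] then [mode_power_envelope()] for
#' every band of a [band_partition()] bank.
#'
#' @param trace a [voltage_trace()]
#' @param bank a [band_partition()] result
#' @param taper_frac passed to [bandpass_mode()]
#' @return object of class `modal_power`: list with `times`, `U` (matrix
#'   `n_times x n_modes` of power envelopes), `centers` \[Hz\], `bank`
#' @export
modal_power <- function(trace, bank, taper_frac = 0) {
  stopifnot(nrow(bank) >= 1)
  U <- vapply(seq_len(nrow(bank)), function(k) {
    mode_power_envelope(bandpass_mode(trace, bank[k, ], taper_frac))$samples
  }, numeric(length(trace$samples)))
  out <- list(times = trace_times(trace), U = U, centers = bank$f_center,
              bank = bank)
  class(out) <- "modal_power"
  out
}

#' Modal energies and energy fractions over a time window
#'
#' Per-mode energy is the trapezoidal integral of the power envelope over
#' `window`; fractions are normalized over the detected modes. The
#' low/high-frequency split at `split_hz` (default 1 kHz) summarizes how
#' much of the event's energy travels in high-order modes.
#'
#' @param power a [modal_power()] result
#' @param window numeric `c(t1, t2)` \[s\], inside the trace support
#' @param split_hz frequency split for the low/high summary \[Hz\]
#' @return list with `energy` \[V^2 s\], `fraction` per mode, and
#'   `split` (named fractions `below`, `above`)
#' @export
modal_energy <- function(power, window, split_hz = 1000) {
  stopifnot(length(window) == 2, window[2] > window[1])
  t <- power$times
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 2) stop("integration window is empty or outside the trace")
  en <- vapply(seq_len(ncol(power$U)), function(k) {
    trapz_num(t[sel], power$U[sel, k])
  }, 0)
  frac <- en / sum(en)
  hi <- power$centers > split_hz
  list(energy = en, fraction = frac,
       split = c(below = sum(frac[!hi]), above = sum(frac[hi])))
}

trapz_num <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
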