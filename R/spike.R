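#' Upsample a trace by linear interpolation
#'
#' Inserts `factor - 1` linearly interpolated samples between neighboring
#' data points (the thresholding step uses 5x upsampling, 20 to 100 kS/s,
#' to avoid digital noise in crossing times). Original samples are
#' preserved exactly at every `factor`-th position; the output has
#' `factor * (n - 1) + 1` samples.
#'
#' @param trace a [voltage_trace()]
#' @param factor integer >= 1
#' @return a [voltage_trace()] at `factor` times the sampling rate
#' @export
upsample_trace <- function(trace, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(trace)
  n <- length(trace$samples)
  t_old <- seq_len(n)
  t_new <- seq(1, n, by = 1 / factor)
  v <- stats::approx(t_old, trace$samples, xout = t_new)$y
  voltage_trace(v, sample_rate = trace$sample_rate * factor,
                V_off = trace$V_off, t0 = trace$t0, units = trace$units,
                gain_label = trace$gain_label)
}

#' Threshold-crossing spike times from a power trace
#'
#' The population spike-encoding model: rapidly adapting mechanoreceptors
#' fire near-single spikes at fast stimulus ramps, so a spike is emitted at
#' every crossing of the power threshold, in both directions (up at the
#' leading edge of an energy burst, down at its trailing edge). Crossing
#' times are linearly interpolated between the bracketing samples.
#'
#' @param power a [voltage_trace()] of nonnegative power samples (squared
#'   offset-corrected voltage, typically upsampled first)
#' @param threshold crossing level, > 0, same units as the power samples
#' @return numeric vector of spike times \[s\], sorted; attribute
#'   `below_floor` flags a threshold under the background level (median of
#'   the power), where the spike count explodes
#' @export
threshold_spikes <- function(power, threshold) {
  stopifnot(inherits(power, "voltage_trace"), threshold > 0,
            all(power$samples >= 0))
  p <- power$samples
  below_floor <- threshold < stats::median(p)
  if (below_floor)
    warning("threshold is below the background power level; ",
            "spike count will explode")
  t <- trace_times(power)
  s <- sign(p - threshold)
  # treat exact hits as crossings on the next move away
  idx <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] == 0 & s[-1] != 0))
  if (!length(idx))
    return(structure(numeric(0), below_floor = below_floor))
  frac <- (threshold - p[idx]) / (p[idx + 1] - p[idx])
  structure(sort(t[idx] + frac * (t[idx + 1] - t[idx])),
            below_floor = below_floor)
}

#' Spike ensemble container
#'
#' @param trials list of numeric spike-time vectors \[s\], one per trial
#' @param t_start start of the analysis window \[s\]
#' @param T window length \[s\] (default 5 ms, the post-collision window in
#'   which the dispersed wave packets arrive)
#' @return object of class `spike_ensemble`
#' @export
spike_ensemble <- function(trials, t_start = 0, T = 5e-3) {
  stopifnot(is.list(trials), length(trials) >= 1, T > 0)
  trials <- lapply(trials, function(x) sort(as.numeric(x)))
  structure(list(trials = trials, t_start = t_start, T = T),
            class = "spike_ensemble")
}

#' @export
print.spike_ensemble <- function(x, ...) {
  ns <- vapply(x$trials, length, 0L)
  cat(sprintf("spike_ensemble: %d trials, %.0f spikes total, window [%g, %g] s\n",
              length(x$trials), sum(ns), x$t_start, x$t_start + x$T))
  invisible(x)
}

#' Raster, PSTH and inter-spike-interval summaries
#'
#' The PSTH counts spikes per time bin pooled over trials. The ISI
#' histogram follows the all-pairs convention: within each trial, the
#' temporal lags between all ordered pairs of spike-containing time bins
#' are counted and the histograms averaged across trials (set
#' `consecutive = TRUE` for the conventional consecutive-interval ISI).
#'
#' @param ensemble a [spike_ensemble()]
#' @param bin bin width \[s\]
#' @param consecutive use consecutive intervals instead of all pairs
#' @return list with `raster` (data.frame `trial`, `time`), `psth`
#'   (data.frame `time` = bin left edge, `count`), and `isi` (data.frame
#'   `lag` \[s\], `mean_count` averaged over trials)
#' @export
trial_statistics <- function(ensemble, bin, consecutive = FALSE) {
  stopifnot(inherits(ensemble, "spike_ensemble"), bin > 0,
            bin <= ensemble$T)
  edges <- seq(ensemble$t_start, ensemble$t_start + ensemble$T, by = bin)
  if (max(edges) < ensemble$t_start + ensemble$T)
    edges <- c(edges, max(edges) + bin)
  nb <- length(edges) - 1L
  raster <- do.call(rbind, lapply(seq_along(ensemble$trials), function(i) {
    ts <- ensemble$trials[[i]]
    ts <- ts[ts >= ensemble$t_start & ts < ensemble$t_start + ensemble$T]
    if (!length(ts)) return(NULL)
    data.frame(trial = i, time = ts)
  }))
  if (is.null(raster))
    raster <- data.frame(trial = integer(), time = numeric())
  counts <- numeric(nb)
  isi_acc <- numeric(nb)            # lags in units of bins: 1 .. nb
  for (i in seq_along(ensemble$trials)) {
    ts <- ensemble$trials[[i]]
    ts <- ts[ts >= ensemble$t_start & ts < ensemble$t_start + ensemble$T]
    bi <- pmin(nb, findInterval(ts, edges))
    counts <- counts + tabulate(bi, nbins = nb)
    occ <- sort(unique(bi))
    if (length(occ) >= 2) {
      lags <- if (consecutive) diff(occ)
      else as.vector(stats::dist(occ, method = "manhattan"))
      isi_acc <- isi_acc + tabulate(round(lags), nbins = nb)
    }
  }
  list(raster = raster,
       psth = data.frame(time = edges[-length(edges)], count = counts),
       isi = data.frame(lag = bin * seq_len(nb),
                        mean_count = isi_acc / length(ensemble$trials)))
}

#' Binarize a spike ensemble into 1-bit words
#'
#' Each trial becomes a binary sequence over `floor(T / dt)` bins: 1 if
#' the bin contains at least one spike, 0 otherwise. Conditional spike
#' probabilities `p(1|t)` are across-trial means per bin; the marginal
#' `p(1)` is their time average.
#'
#' @param ensemble a [spike_ensemble()]
#' @param dt bin width \[s\]; must not exceed `T` and must be at least
#'   `min_dt` (the upsampled sampling period -- finer bins than the signal
#'   grid would be fictitious precision)
#' @param T analysis window \[s\]; defaults to the ensemble's window
#' @param min_dt finest admissible bin \[s\] (default 10 us, the 100 kS/s
#'   grid)
#' @return object of class `word_sequence`: list with `words` (matrix
#'   `n_trials x n_bins` of 0/1), `dt`, `p1_t` (per-bin spike probability),
#'   `p1` (marginal)
#' @export
binarize <- function(ensemble, dt, T = ensemble$T, min_dt = 1e-5) {
  stopifnot(inherits(ensemble, "spike_ensemble"), dt > 0, dt <= T)
  if (dt < min_dt - 1e-15)
    stop(sprintf("bin width %g s is below the sampling period %g s", dt,
                 min_dt))
  nb <- floor(T / dt)
  words <- t(vapply(ensemble$trials, function(ts) {
    ts <- ts[ts >= ensemble$t_start & ts < ensemble$t_start + nb * dt]
    bi <- floor((ts - ensemble$t_start) / dt) + 1L
    as.integer(tabulate(bi, nbins = nb) > 0)
  }, integer(nb)))
  if (nb == 1) words <- matrix(words, ncol = 1)
  p1_t <- colMeans(words)
  structure(list(words = words, dt = dt, p1_t = p1_t, p1 = mean(p1_t),
                 T = nb * dt),
            class = "word_sequence")
}

entropy_bits <- function(p) {
  p <- c(p, 1 - p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Direct-method mutual information of a word sequence
#'
#' Total entropy `S_total = -sum_i p(i) log2 p(i)` over the word values (0
#' and 1 for single-bit words); noise entropy `S_noise` is the entropy of
#' `p(i|t)` averaged over time bins; the mutual information between the
#' stimulus time course and the words is `I = S_total - S_noise` (with the
#' `0 log 0 = 0` convention). Rates are `I / dt` \[bits/s\] and `I` per
#' mean spike count per bin \[bits/spike\].
#'
#' @param words a [binarize()] result
#' @return object of class `info_estimate`: list with `S_total`, `S_noise`,
#'   `I` \[bits/word\], `rate_bits_s`, `bits_per_spike`, `dt`, `method`
#' @export
direct_information <- function(words) {
  stopifnot(inherits(words, "word_sequence"))
  S_total <- entropy_bits(words$p1)
  S_noise <- mean(vapply(words$p1_t, entropy_bits, 0))
  I <- S_total - S_noise
  mean_spikes_per_bin <- mean(words$words)
  structure(list(S_total = S_total, S_noise = S_noise, I = I,
                 rate_bits_s = I / words$dt,
                 bits_per_spike = if (mean_spikes_per_bin > 0)
                   I / mean_spikes_per_bin else NA_real_,
                 dt = words$dt, method = "direct"),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf(
    "info_estimate (%s): S_total = %.4g, S_noise = %.4g, I = %.4g bits/word (%.4g bits/s)\n",
    x$method, x$S_total, x$S_noise, x$I, x$rate_bits_s))
  invisible(x)
}

#' Jackknife mutual information estimate
#'
#' Leave-one-out direct-method estimates `I_(-j)` over the `N` trials,
#' combined into the standard bias-corrected jackknife value
#' `I_JK = N I_DM - (N - 1) mean(I_(-j))`. The relative deviation between
#' the jackknife and direct estimates is the sampling-bias diagnostic: for
#' low trial-to-trial variability the two agree to a few percent.
#'
#' @param ensemble a [spike_ensemble()] with at least 3 trials
#' @param dt bin width \[s\]
#' @param T analysis window \[s\]
#' @return an `info_estimate` (method `"jackknife"`) with extra fields
#'   `I_direct`, `loo` (the leave-one-out values) and `rel_dev`
#'   (`|I_JK - I_DM| / I_DM`, `NA` when `I_DM` is 0)
#' @export
jackknife_information <- function(ensemble, dt, T = ensemble$T) {
  stopifnot(inherits(ensemble, "spike_ensemble"),
            length(ensemble$trials) >= 3)
  N <- length(ensemble$trials)
  full <- direct_information(binarize(ensemble, dt, T))
  loo <- vapply(seq_len(N), function(j) {
    e <- spike_ensemble(ensemble$trials[-j], ensemble$t_start, ensemble$T)
    direct_information(binarize(e, dt, T))$I
  }, 0)
  I_jk <- N * full$I - (N - 1) * mean(loo)
  mean_spikes_per_bin <- mean(binarize(ensemble, dt, T)$words)
  structure(list(S_total = full$S_total, S_noise = full$S_total - I_jk,
                 I = I_jk, rate_bits_s = I_jk / dt,
                 bits_per_spike = if (mean_spikes_per_bin > 0)
                   I_jk / mean_spikes_per_bin else NA_real_,
                 dt = dt, method = "jackknife",
                 I_direct = full$I, loo = loo,
                 rel_dev = if (full$I != 0)
                   abs(I_jk - full$I) / full$I else NA_real_),
            class = "info_estimate")
}

#' Mutual information rate as a function of bin size
#'
#' Direct-method estimates across a list of bin widths, as used to probe
#' the temporal precision of the spike bar code: the rate keeps growing as
#' bins shrink until the bin size reaches the spike jitter scale, then
#' plateaus.
#'
#' @param ensemble a [spike_ensemble()]
#' @param bins numeric vector of bin widths \[s\]
#' @param T analysis window \[s\]
#' @param min_dt finest admissible bin, passed to [binarize()]
#' @return data.frame: `dt`, `S_total`, `S_noise`, `I`, `rate_bits_s`,
#'   `bits_per_spike`, plus `rate_decreasing` flag marking bins where the
#'   rate dropped relative to the next-coarser bin (a sanity flag, not an
#'   error: estimator bias can produce it)
#' @export
info_vs_binsize <- function(ensemble, bins, T = ensemble$T, min_dt = 1e-5) {
  bins <- sort(bins, decreasing = TRUE)
  rows <- lapply(bins, function(b) {
    est <- direct_information(binarize(ensemble, b, T, min_dt = min_dt))
    data.frame(dt = b, S_total = est$S_total, S_noise = est$S_noise,
               I = est$I, rate_bits_s = est$rate_bits_s,
               bits_per_spike = est$bits_per_spike)
  })
  out <- do.call(rbind, rows)
  out$rate_decreasing <- c(FALSE, diff(out$rate_bits_s) < 0)
  out
}
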