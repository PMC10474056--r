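#' Resonant modal peaks from a spectrogram cross-section
#'
#' Takes the magnitude slice of the spectrogram at a fixed delay after the
#' event onset (1 ms by default, early enough that fast-decaying high
#' modes are still above the floor) and returns the ordered resonant
#' frequencies of its local maxima via [band_partition()].
#'
#' When the trace contains a pre-onset baseline (at least one wavelet
#' width before `onset`), candidate peaks are additionally screened
#' against the per-frequency noise power of that baseline: under the
#' noise-only null the squared coefficient magnitude is exponentially
#' distributed around the baseline mean, so a peak is kept only if its
#' exceedance probability (Bonferroni-corrected over the frequency grid)
#' is below `alpha`. This gives a controlled false-alarm rate -- a
#' noise-only trace yields an empty list -- while leaving real modal
#' peaks, which sit far above the microphone noise, untouched.
#'
#' @param spect a [cmw_spectrogram()]
#' @param delay delay after `onset` \[s\]
#' @param onset event onset time \[s\]
#' @param alpha familywise false-alarm rate of the baseline screen
#' @param ... passed to [band_partition()]
#' @return numeric vector of resonant frequencies \[Hz\] (possibly empty),
#'   with the full [band_partition()] bank as attribute `bank`
#' @export
detect_modal_peaks <- function(spect, delay = 1e-3, onset = 0,
                               alpha = 0.01, ...) {
  slice <- spectrogram_slice(spect, onset + delay)
  bank <- suppressWarnings(band_partition(slice, ...))
  if (nrow(bank)) {
    pre <- vapply(bank$f_center, function(f) {
      ki <- which.min(abs(spect$freqs - f))
      sel <- spect$times < onset - spect$coi[ki]
      if (sum(sel) < 20) return(NA_real_)
      mean(Mod(spect$coefs[ki, sel])^2)
    }, 0)
    q <- stats::qexp(1 - alpha / length(spect$freqs))
    keep <- is.na(pre) | bank$peak_mag^2 > pre * q
    bank <- bank[keep, , drop = FALSE]
    if (nrow(bank)) bank$j <- seq_len(nrow(bank))
    rownames(bank) <- NULL
  }
  structure(bank$f_center, bank = bank)
}

#' Damping correction: resonant to natural frequency
#'
#' `f_n = f_R / sqrt(1 - zeta^2)`. For the damping ratios seen on whiskers
#' (at most ~0.35 for a heavily damped fundamental) the adjustment is below
#' 10% and negligible for high-order modes.
#'
#' @param f_R resonant (spectral-peak) frequency \[Hz\]
#' @param zeta damping ratio in `[0, 1)`
#' @return natural frequency \[Hz\]
#' @export
correct_natural_frequency <- function(f_R, zeta) {
  stopifnot(all(zeta >= 0))
  if (any(zeta >= 1))
    stop("zeta >= 1: overdamped mode has no resonant peak to correct")
  f_R / sqrt(1 - zeta^2)
}

#' Damping ratio from frequency and decay time
#'
#' `zeta = 1 / (omega_n tau) = 1 / (2 pi f_n tau)`, with `tau` the
#' amplitude decay time constant; the modal Q-factor is `1 / (2 zeta)`.
#'
#' @param f_n natural frequency \[Hz\]
#' @param tau amplitude decay time constant \[s\]
#' @return damping ratio (dimensionless)
#' @export
damping_ratio <- function(f_n, tau) {
  stopifnot(all(f_n > 0), all(tau > 0))
  1 / (2 * pi * f_n * tau)
}

#' Fit a damped harmonic to a filtered trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `A exp(-t / tau) sin(omega t + phi)` to an offset-corrected bandpassed
#' trace. This is the low-frequency route for damping estimation (below
#' ~200 Hz the wavelet's time resolution cannot follow the decay, so the
#' time-domain fit is used instead). Start values come from the analytic
#' envelope (log-linear fit for `A`, `tau`) and the FFT peak (for `omega`),
#' with the best of eight phase starts.
#'
#' @param trace a [voltage_trace()] (bandpassed, offset removed)
#' @param t_start fit window start \[s\] relative to the trace start
#' @return object of class `damped_sinusoid_fit`: list with `A`, `tau`
#'   \[s\], `omega_n` \[rad/s\], `f_n` \[Hz\], `phi`, `zeta`
#'   (`= 1/(omega_n tau)`), `Q`, standard errors `se`, `residual_rms`,
#'   `converged`, and `low_confidence` (fewer than 3 visible periods)
#' @export
fit_damped_sinusoid <- function(trace, t_start = 0) {
  x <- offset_correct(trace)
  fs <- trace$sample_rate
  t <- (seq_along(x) - 1L) / fs
  sel <- t >= t_start
  t <- t[sel] - t_start; x <- x[sel]
  n <- length(x)
  # start values
  spec <- Mod(stats::fft(x))[1:(n %/% 2)]
  f0 <- max(1, which.max(spec[-1])) * fs / n
  env <- Mod(analytic_signal(x))
  core <- which(env > max(env) / 20)
  ef <- stats::lm(log(env[core]) ~ t[core])
  tau0 <- max(unname(-1 / stats::coef(ef)[2]), 10 / fs)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- n / fs
  A0 <- unname(exp(stats::coef(ef)[1]))
  best <- NULL
  for (phi0 in seq(0, 2 * pi - pi / 4, by = pi / 4)) {
    fit <- try(minpack.lm::nlsLM(
      x ~ A * exp(-t / tau) * sin(omega * t + phi),
      start = list(A = A0, tau = tau0, omega = 2 * pi * f0, phi = phi0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(A = NA, tau = NA, omega_n = NA, f_n = NA,
                          phi = NA, zeta = NA, Q = NA, se = NULL,
                          residual_rms = NA, converged = FALSE,
                          low_confidence = TRUE),
                     class = "damped_sinusoid_fit"))
  }
  cf <- stats::coef(best)
  omega <- abs(cf[["omega"]]); tau <- abs(cf[["tau"]])
  zeta <- 1 / (omega * tau)
  periods <- min(tau * 3, n / fs) * omega / (2 * pi)
  out <- list(A = abs(cf[["A"]]), tau = tau, omega_n = omega,
              f_n = omega / (2 * pi), phi = cf[["phi"]] %% (2 * pi),
              zeta = zeta, Q = 1 / (2 * zeta),
              se = summary(best)$coefficients[, "Std. Error"],
              residual_rms = sqrt(mean(stats::residuals(best)^2)),
              converged = best$convInfo$isConv %||% TRUE,
              low_confidence = periods < 3)
  class(out) <- "damped_sinusoid_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Damping ratio from the wavelet ridge slope
#'
#' High-frequency route (valid above ~200 Hz where the wavelet's time
#' resolution is a few ms or better): at the mode's central frequency the
#' log magnitude of the wavelet coefficients decays linearly in time with
#' slope `-zeta * omega_n`, so a straight-line fit of `ln|W|` over the fit
#' window gives the damping ratio directly.
#'
#' @param spect a [cmw_spectrogram()]
#' @param f_n modal (natural) frequency \[Hz\]; the nearest grid frequency
#'   row is used
#' @param window fit window `c(t1, t2)` \[s\]; the default starts
#'   `max(1 ms, 2.5 wavelet SD)` after `onset` (clear of the onset
#'   transient smeared by the wavelet) and ends where the ridge falls
#'   `drop_db` below its window maximum, capped at the cone-of-influence
#'   margin before the trace end
#' @param onset event onset time \[s\]
#' @param drop_db ridge drop defining the default window end
#' @return list with `zeta`, `lambda` (decay rate `1/tau` \[1/s\]), `tau`,
#'   `Q`, `slope_se`, `window`, `f_used`
#' @export
damping_from_wavelet_slope <- function(spect, f_n, window = NULL,
                                       onset = 0, drop_db = 30) {
  if (f_n < 200)
    warning("wavelet-slope damping below 200 Hz is unreliable; ",
            "use fit_damped_sinusoid")
  k <- which.min(abs(spect$freqs - f_n))
  ridge <- abs(spect$coefs[k, ])
  tt <- spect$times
  coi <- spect$coi[k]
  if (is.null(window)) {
    sig <- cmw_sigma_t(spect$freqs[k], spect$center_freq, spect$bandwidth)
    t1 <- max(onset + max(1e-3, 2.5 * sig), min(tt) + coi)
    after <- which(tt >= t1)
    if (length(after) < 5) stop("onset too late in the trace")
    peak <- max(ridge[after])
    below <- after[20 * log10(ridge[after] / peak) < -drop_db]
    t2 <- if (length(below)) tt[below[1]] else max(tt)
    window <- c(t1, min(t2, max(tt) - coi))
  }
  if (window[1] < min(tt) + coi || window[2] > max(tt) - coi)
    stop(sprintf(paste0("fit window [%.4g, %.4g] s overlaps the cone of ",
                        "influence (margin %.4g s at %.4g Hz)"),
                 window[1], window[2], coi, spect$freqs[k]))
  sel <- tt >= window[1] & tt <= window[2]
  if (sum(sel) < 5) stop("fit window contains fewer than 5 samples")
  fit <- stats::lm(log(ridge[sel]) ~ tt[sel])
  lambda <- -stats::coef(fit)[[2]]
  omega <- 2 * pi * f_n
  list(zeta = lambda / omega, lambda = lambda, tau = 1 / lambda,
       Q = omega / (2 * lambda),
       slope_se = summary(fit)$coefficients[2, 2],
       window = window, f_used = spect$freqs[k])
}

#' Per-mode group delay and group velocity from power envelopes
#'
#' Modal group delay is the arrival time of the power-envelope peak of the
#' bandpass-filtered mode, relative to the event onset; group velocity is
#' `propagation_length / delay`.
#'
#' @param power a [modal_power()] result
#' @param onset event onset time \[s\] (must be given explicitly; with
#'   synthetic data this is the collision time)
#' @param propagation_length distance from excitation to base \[m\]
#' @return data.frame: `j`, `f_center` \[Hz\], `delay` \[s\], `v_g` \[m/s\]
#'   (`NA` when `propagation_length == 0` or `delay <= 0`), `multi_peak`
#'   flag (envelope has secondary maxima above half the main peak)
#' @export
group_delay_and_velocity <- function(power, onset, propagation_length) {
  stopifnot(!missing(onset), is.finite(onset), propagation_length >= 0)
  t <- power$times
  after <- which(t >= onset)
  if (!length(after)) stop("onset beyond the trace")
  res <- lapply(seq_len(ncol(power$U)), function(k) {
    u <- power$U[after, k]
    imax <- which.max(u)
    t_pk <- t[after][imax]
    if (imax > 1 && imax < length(u)) {
      # parabolic vertex through the three samples around the maximum
      y <- u[(imax - 1):(imax + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (denom < 0) {
        dt_s <- t[after][imax + 1] - t[after][imax]
        t_pk <- t_pk + 0.5 * (y[1] - y[3]) / denom * dt_s
      }
    }
    delay <- t_pk - onset
    pk <- u[imax]
    lm_idx <- which(diff(sign(diff(u))) < 0) + 1L
    multi <- sum(u[lm_idx] > pk / 2) > 1
    vg <- if (propagation_length > 0 && delay > 0)
      propagation_length / delay else NA_real_
    data.frame(j = k, f_center = power$centers[k], delay = delay,
               v_g = vg, multi_peak = multi)
  })
  do.call(rbind, res)
}

#' Fit Young's modulus to a whisker trimming series
#'
#' One-parameter nonlinear least squares over all `(l, j, f_n)` rows of a
#' trimming series: the tapered-beam frequency law predicts every mode of
#' every truncation once the geometry is fixed, leaving the Young's modulus
#' `E` as the single adjustable parameter (frequencies scale as `sqrt(E)`).
#' Dimensionless coefficients are obtained from [solve_eigenmodes()] per
#' distinct truncated length.
#'
#' @param series data.frame with columns `l` \[m\], `j` (mode index), `f_n`
#'   \[Hz\]; at least 2 rows spanning more than one `(l, j)` combination
#' @param geom a [whisker_geometry()] carrying `S_tot`, `R_b`, `r_t`,
#'   `rho` (its `E` is ignored)
#' @param grid_size eigensolver grid
#' @param E_start starting value \[Pa\]
#' @return list with `E` \[Pa\], `se` \[Pa\], `pearson_r` (model vs data),
#'   `fitted` (data.frame `l`, `j`, `f_n`, `f_model`), and the `nls` fit
#' @export
fit_youngs_modulus <- function(series, geom, grid_size = 300, E_start = 2e9) {
  stopifnot(all(c("l", "j", "f_n") %in% names(series)))
  if (nrow(series) < 2 ||
      (length(unique(series$l)) == 1 && length(unique(series$j)) == 1))
    stop("singular design: need at least two distinct (l, j) observations")
  lens <- sort(unique(series$l))
  # per-length mode frequencies at unit E; f = sqrt(E) * g
  g_tab <- lapply(lens, function(li) {
    gi <- whisker_geometry(S_tot = geom$S_tot, R_b = geom$R_b, r_t = geom$r_t,
                           l = li, E = 1, rho = geom$rho,
                           A_curv = geom$A_curv * 1)
    ms <- solve_eigenmodes(gi, n_modes = min(30, max(series$j)),
                           grid_size = grid_size, check = FALSE)
    ms$table$f_j
  })
  names(g_tab) <- sprintf("%.12g", lens)
  g <- mapply(function(li, ji) g_tab[[sprintf("%.12g", li)]][ji],
              series$l, series$j)
  df <- data.frame(f_n = series$f_n, g = g)
  fit <- minpack.lm::nlsLM(f_n ~ sqrt(E) * g, data = df,
                           start = list(E = E_start),
                           lower = 0,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  E_hat <- stats::coef(fit)[["E"]]
  f_model <- sqrt(E_hat) * g
  list(E = E_hat, se = summary(fit)$coefficients[1, 2],
       pearson_r = stats::cor(f_model, series$f_n),
       fitted = data.frame(l = series$l, j = series$j, f_n = series$f_n,
                           f_model = f_model),
       fit = fit)
}
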