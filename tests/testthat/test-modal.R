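test_that("modal peaks of a 10-mode slip-off land within one grid step", {
  fx <- fx_slipoff()
  pk <- detect_modal_peaks(fx$spect, delay = 10e-3, onset = fx$onset)
  f_d <- fx$modes$table$f_j * sqrt(1 - fx$zeta^2)
  expect_length(pk, 10)
  step <- exp(log(6000 / 30) / 599)
  expect_lt(max(abs(log(pk / f_d))), log(step))
  expect_true(all(diff(pk) > 0))
})

test_that("pure noise yields an empty peak list", {
  set.seed(7)
  trn <- voltage_trace(rnorm(8000, 0, 1e-3), 20000)
  spn <- cmw_spectrogram(trn, f_min = 30, f_max = 6000, n_freq = 300)
  pk <- suppressWarnings(detect_modal_peaks(spn, delay = 1e-3, onset = 0.2))
  expect_length(pk, 0)
})

test_that("a dense mouse-like mode ladder up to 9.4 kHz yields >= 14 peaks", {
  geom <- fx_mouse_geom()
  ms <- solve_eigenmodes(geom, n_modes = 16, grid_size = 400, check = FALSE)
  f_j <- ms$table$f_j
  keep <- f_j < 9500
  zeta <- pmin(0.3, 1.5 / f_j[keep])
  tr <- generate_slipoff_trace(f_j[keep], zeta = zeta, amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 1e-4,
                                                     seed = 12),
                               duration = 0.6, t_onset = 0.1)
  sp <- cmw_spectrogram(tr, f_min = 40, f_max = 9800, n_freq = 700)
  pk <- detect_modal_peaks(sp, delay = 8e-3, onset = 0.1)
  expect_gte(length(pk), 14)
})

test_that("damping correction follows f_R / sqrt(1 - zeta^2)", {
  expect_equal(correct_natural_frequency(100, 0), 100)
  # at the heaviest observed damping the adjustment stays below 10%
  expect_equal(correct_natural_frequency(1, 0.35) - 1, 0.0675,
               tolerance = 1e-3)
  expect_lt(correct_natural_frequency(1, 0.35) - 1, 0.10)
  expect_equal(correct_natural_frequency(1, 0.153), 1.0119,
               tolerance = 1e-4)
  # inverse round trip is the identity
  f_n <- correct_natural_frequency(82, 0.3)
  expect_equal(f_n * sqrt(1 - 0.3^2), 82, tolerance = 1e-12)
  expect_error(correct_natural_frequency(100, 1), "overdamped")
})

test_that("damping_ratio and Q-factor conventions are consistent", {
  z <- damping_ratio(82, 0.0127)
  expect_equal(z, 1 / (2 * pi * 82 * 0.0127), tolerance = 1e-12)
  expect_equal(round(z, 3), 0.153)
  # Q = 1 / (2 zeta)
  fit <- list(zeta = z)
  expect_equal(1 / (2 * z) * 2 * z, 1)
})

test_that("damped-sinusoid fit recovers the worked low-frequency example", {
  tr <- generate_slipoff_trace(82, zeta = damping_ratio(82, 0.0127),
                               amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 1e-3,
                                                     seed = 3),
                               duration = 0.2)
  fit <- fit_damped_sinusoid(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$f_n - 82), 3)                      # 82 +/- 3 regime
  expect_equal(fit$tau, 0.0127, tolerance = 0.02)
  expect_lt(abs(fit$zeta - 0.153), 0.01)
  expect_equal(fit$Q, 1 / (2 * fit$zeta))
})

test_that("an effectively undamped tone fits with zeta < 1e-4", {
  tr <- generate_slipoff_trace(120, zeta = 1 / (2 * pi * 120 * 1e6),
                               amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 0),
                               duration = 0.3)
  fit <- fit_damped_sinusoid(tr)
  expect_lt(fit$zeta, 1e-4)
})

test_that("damped fits recover a 3x3 (f, tau) grid at 40 dB SNR", {
  for (f0 in c(80, 120, 180)) {
    for (tau in c(0.015, 0.04, 0.09)) {
      tr <- generate_slipoff_trace(
        f0, zeta = damping_ratio(f0, tau), amplitudes = 1,
        cfg = ensemble_config(noise_floor = 0.01, seed = round(f0 + tau * 1e4)),
        duration = 0.4)
      fit <- fit_damped_sinusoid(tr)
      expect_equal(fit$f_n, f0, tolerance = 0.02)
      expect_equal(fit$tau, tau, tolerance = 0.05)
    }
  }
})

test_that("wavelet-slope damping recovers injected values above 200 Hz", {
  for (p in list(c(1000, 0.01), c(300, 1 / 30), c(2500, 0.004))) {
    f0 <- p[1]; z0 <- p[2]
    tr <- generate_slipoff_trace(f0, zeta = z0, amplitudes = 1,
                                 cfg = ensemble_config(noise_floor = 0),
                                 duration = 0.5, t_onset = 0.08)
    sp <- cmw_spectrogram(tr, f_min = 150, f_max = 5000, n_freq = 150)
    est <- damping_from_wavelet_slope(sp, f0, onset = 0.08)
    expect_equal(est$zeta, z0, tolerance = 0.10)
    expect_equal(est$Q, 1 / (2 * est$zeta), tolerance = 1e-9)
  }
})

test_that("an undamped tone has wavelet slope consistent with zero", {
  tr <- generate_slipoff_trace(700, zeta = 1e-6, amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 0),
                               duration = 0.5, t_onset = 0.08)
  sp <- cmw_spectrogram(tr, f_min = 300, f_max = 1500, n_freq = 80)
  est <- damping_from_wavelet_slope(sp, 700, window = c(0.12, 0.4))
  expect_lt(abs(est$lambda), 3 * est$slope_se + 0.5)
})

test_that("fit windows inside the cone of influence are rejected", {
  tr <- generate_slipoff_trace(800, zeta = 0.01, amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 0),
                               duration = 0.3, t_onset = 0.05)
  sp <- cmw_spectrogram(tr, f_min = 300, f_max = 1500, n_freq = 60)
  expect_error(damping_from_wavelet_slope(sp, 800,
                                          window = c(0.001, 0.05)),
               "cone of influence")
})

test_that("zeta proportional to 1/f appears with log-log slope -1 and rising Q", {
  fx <- fx_slipoff()
  f_j <- fx$modes$table$f_j
  sel <- which(f_j > 250)
  z_est <- vapply(sel, function(k)
    damping_from_wavelet_slope(fx$spect, f_j[k], onset = fx$onset)$zeta, 0)
  fit <- lm(log(z_est) ~ log(f_j[sel]))
  expect_equal(coef(fit)[[2]], -1, tolerance = 0.1)
  expect_equal(z_est, fx$zeta[sel], tolerance = 0.1)
  Q <- 1 / (2 * z_est)
  expect_true(all(diff(Q) > 0))
})

test_that("the two damping regimes agree on a 300 Hz tone", {
  z0 <- 0.02
  tr <- generate_slipoff_trace(300, zeta = z0, amplitudes = 1,
                               cfg = ensemble_config(noise_floor = 1e-4,
                                                     seed = 6),
                               duration = 0.8, t_onset = 0.15)
  sp <- cmw_spectrogram(tr, f_min = 120, f_max = 900, n_freq = 100)
  z_wav <- damping_from_wavelet_slope(sp, 300, onset = 0.15)$zeta
  # time-domain fit on the post-onset segment
  post <- voltage_trace(tr$samples[trace_times(tr) >= 0.15],
                        sample_rate = tr$sample_rate)
  z_fit <- fit_damped_sinusoid(post)$zeta
  expect_equal(z_wav, z_fit, tolerance = 0.1)
  expect_equal(z_fit, z0, tolerance = 0.1)
})

test_that("group delays and velocities follow the dispersion fixture", {
  geom <- fx_rat_geom()
  ms <- fx_rat_modes(9)
  f_j <- ms$table$f_j
  L <- 21e-3
  tr <- generate_texture_sweep(ms, event_rate = 2,
                               cfg = ensemble_config(noise_floor = 1e-5,
                                                     seed = 6),
                               duration = 1, dispersion = "on", geom = geom,
                               propagation_length = L, event_times = 0.4,
                               partitions = matrix(rep(1 / 9, 9), 1),
                               min_cycles = 4)
  mp <- modal_power(tr, mode_band_bank(ms, c(20, 9000)))
  gd <- group_delay_and_velocity(mp, onset = 0.4, propagation_length = L)
  vg_true <- group_velocity(geom$E, geom$R_b, geom$rho, 2 * pi * f_j)
  expect_lt(max(abs(gd$v_g - vg_true) / vg_true), 0.10)
  # the modal delays recover the injected dispersive arrivals
  expect_equal(gd$delay, attr(tr, "event_log")$arrival_delays,
               tolerance = 0.1)
  # fundamental arrives milliseconds after the high modes
  expect_gt(gd$delay[1] - gd$delay[9], 2e-3)
  # onset must be given explicitly
  expect_error(group_delay_and_velocity(mp, propagation_length = L),
               "onset")
})

test_that("two packets injected 3 ms apart are measured 3 ms apart", {
  fs <- 20000
  t <- (0:19999) / fs
  mk <- function(tc, f0) exp(-(t - tc)^2 / (2 * 2e-3^2)) * sin(2 * pi * f0 * t)
  tr <- voltage_trace(mk(0.40, 400) + mk(0.403, 3000), fs)
  mp <- modal_power(tr, mode_band_bank(c(400, 3000)))
  gd <- group_delay_and_velocity(mp, onset = 0.39, propagation_length = 0)
  expect_equal(gd$delay[1] - gd$delay[2], -3e-3, tolerance = 1 / fs)
  expect_true(all(is.na(gd$v_g)))
})

test_that("Young's modulus is a one-parameter fit recovering the truth", {
  geom <- fx_mouse_geom()
  lens <- seq(12, 21.5, length.out = 7) * 1e-3
  series <- do.call(rbind, lapply(lens, function(li) {
    gi <- whisker_geometry(S_tot = geom$S_tot, R_b = geom$R_b, r_t = 0,
                           l = li, E = geom$E, rho = geom$rho)
    msi <- solve_eigenmodes(gi, n_modes = 7, grid_size = 250, check = FALSE)
    data.frame(l = li, j = 1:7, f_n = msi$table$f_j)
  }))
  # noiseless: inverse-crime recovery to 0.1%
  fit0 <- fit_youngs_modulus(series, geom, grid_size = 250)
  expect_equal(fit0$E, geom$E, tolerance = 1e-3)
  expect_length(coef(fit0$fit), 1)         # exactly one adjustable parameter
  # 1% multiplicative frequency noise on all 49 points: E within 2%
  set.seed(11)
  noisy <- series
  noisy$f_n <- series$f_n * (1 + 0.01 * rnorm(nrow(series)))
  fit <- fit_youngs_modulus(noisy, geom, grid_size = 250)
  expect_equal(fit$E, geom$E, tolerance = 0.02)
  expect_gt(fit$pearson_r, 0.99)
  expect_gt(fit$se, 0)
  # degenerate designs are rejected
  expect_error(fit_youngs_modulus(series[1, ], geom), "singular")
})
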