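tone_trace <- function(f, dur = 0.4, fs = 20000, A = 1, V_off = 0,
                       zeta = 0, t_onset = 0) {
  generate_slipoff_trace(f, zeta = zeta, amplitudes = A,
                         cfg = ensemble_config(noise_floor = 0),
                         duration = dur, sample_rate = fs, V_off = V_off,
                         t_onset = t_onset)
}

test_that("spectrogram ridge tracks a pure tone at the right magnitude", {
  tr <- tone_trace(1000)
  sp <- cmw_spectrogram(tr, f_min = 200, f_max = 4000, n_freq = 300)
  step <- exp(log(4000 / 200) / 299)
  for (tt in c(0.1, 0.2, 0.3)) {
    sl <- spectrogram_slice(sp, tt)
    f_ridge <- sl$freq[which.max(sl$mag)]
    expect_lt(abs(log(f_ridge / 1000)), log(step))
    # L1-normalized daughters: unit tone -> ridge magnitude 1/2 (up to
    # the sub-grid-step offset of the nearest analysis frequency)
    expect_equal(max(sl$mag), 0.5, tolerance = 0.01)
  }
})

test_that("ridge decay rate of a damped tone equals the amplitude decay", {
  tau <- 0.02                       # amplitude decay time
  f0 <- 800
  zeta <- 1 / (2 * pi * f0 * tau)
  tr <- tone_trace(f0, zeta = zeta, t_onset = 0.05)
  sp <- cmw_spectrogram(tr, f_min = 300, f_max = 2500, n_freq = 200)
  k <- which.min(abs(sp$freqs - f0))
  sel <- sp$times >= 0.07 & sp$times <= 0.12
  slope <- -coef(lm(log(abs(sp$coefs[k, sel])) ~ sp$times[sel]))[[2]]
  expect_equal(slope, 1 / tau, tolerance = 0.05)
})

test_that("two tones two octaves apart give two independent ridges", {
  fs <- 20000
  cfg <- ensemble_config(noise_floor = 0)
  both <- generate_slipoff_trace(c(500, 2000), zeta = 0, amplitudes = c(1, 1),
                                 cfg = cfg, duration = 0.4)
  sp <- cmw_spectrogram(both, f_min = 200, f_max = 5000, n_freq = 300)
  sl <- spectrogram_slice(sp, 0.2)
  m500 <- max(sl$mag[abs(log(sl$freq / 500)) < 0.2])
  m2000 <- max(sl$mag[abs(log(sl$freq / 2000)) < 0.2])
  expect_equal(m500, 0.5, tolerance = 0.1)
  expect_equal(m2000, 0.5, tolerance = 0.1)
})

test_that("spectrogram magnitude is invariant to the DC offset", {
  tr0 <- tone_trace(600)
  trV <- tone_trace(600, V_off = 1.423)
  sp0 <- cmw_spectrogram(tr0, f_min = 200, f_max = 2000, n_freq = 100)
  spV <- cmw_spectrogram(trV, f_min = 200, f_max = 2000, n_freq = 100)
  expect_equal(abs(spV$coefs), abs(sp0$coefs), tolerance = 1e-8)
})

test_that("too-short traces for the requested band are rejected", {
  short <- voltage_trace(rnorm(400), 20000)   # 20 ms
  expect_error(cmw_spectrogram(short, f_min = 2, f_max = 100, n_freq = 10),
               "too short")
})

test_that("band partition finds injected eigenfrequency peaks", {
  fx <- fx_slipoff()
  sl <- spectrogram_slice(fx$spect, fx$onset + 10e-3)
  bank <- band_partition(sl)
  f_d <- fx$modes$table$f_j * sqrt(1 - fx$zeta^2)
  step <- exp(log(6000 / 30) / 599)
  for (f in f_d[f_d > 40]) {
    expect_true(any(abs(log(bank$f_center / f)) < 1.5 * log(step)),
                label = sprintf("peak near %.0f Hz", f))
  }
  expect_true(all(bank$f_lo < bank$f_center & bank$f_center < bank$f_hi))
  # bands are ordered and non-overlapping
  expect_true(all(diff(as.vector(t(bank[, c("f_lo", "f_hi")]))) >= 0))
  # bandwidth increases with ascending frequency overall
  bw <- bank$f_hi - bank$f_lo
  expect_gt(bw[nrow(bank)], bw[1])
})

test_that("high-contrast slices report edge minima tens of dB below peaks", {
  fx <- fx_slipoff()
  sl <- spectrogram_slice(fx$spect, fx$onset + 10e-3)
  bank <- band_partition(sl)
  expect_gt(max(bank$contrast_db), 20)
})

test_that("single peak with monotone flanks spans the analyzed range", {
  tr <- tone_trace(700)
  sp <- cmw_spectrogram(tr, f_min = 300, f_max = 1600, n_freq = 150)
  bank <- band_partition(spectrogram_slice(sp, 0.2))
  expect_equal(nrow(bank), 1)
  expect_lt(bank$f_lo, 330)
  expect_gt(bank$f_hi, 1450)
})

test_that("a flat noise-free slice yields an empty bank with a warning", {
  sl <- data.frame(freq = exp(seq(log(10), log(1000), length.out = 200)),
                   mag = rep(1e-6, 200))
  expect_warning(bank <- band_partition(sl), "no modal peaks")
  expect_equal(nrow(bank), 0)
})

test_that("FFT bandpass passes in-band tones and kills out-of-band tones", {
  tr <- tone_trace(500, dur = 0.3)
  inband <- bandpass_mode(tr, c(400, 600))
  core <- 1000:5000
  expect_gt(max(abs(inband$samples[core])) / 1, 0.99)
  out <- bandpass_mode(tr, c(1000, 2000))
  expect_lt(max(abs(out$samples[core])), 1e-3)   # >= 60 dB down
  # two-tone separation: each band keeps its own tone, < 1% cross-talk
  two <- generate_slipoff_trace(c(500, 3000), zeta = 0, amplitudes = 1,
                                cfg = ensemble_config(noise_floor = 0),
                                duration = 0.3)
  b1 <- bandpass_mode(two, c(400, 600))$samples[core]
  b2 <- bandpass_mode(two, c(2500, 3500))$samples[core]
  t <- (core - 1) / 20000
  ref1 <- sin(2 * pi * 500 * t + pi / 2)
  ref2 <- sin(2 * pi * 3000 * t + pi / 2)
  expect_lt(max(abs(b1 - ref1)), 0.01)
  expect_lt(max(abs(b2 - ref2)), 0.01)
  expect_error(bandpass_mode(tr, c(500, 11000)), "Nyquist")
})

test_that("power envelope squares the amplitude and doubles decay rates", {
  tr <- tone_trace(800, A = 0.7, dur = 0.3)
  env <- mode_power_envelope(bandpass_mode(tr, c(600, 1000)))
  core <- 1000:5000
  expect_equal(mean(env$samples[core]), 0.49, tolerance = 0.05)
  expect_lt(diff(range(env$samples[core])) / 0.49, 0.05)  # ripple < 5%
  # damped tone: envelope decays at twice the amplitude rate
  tau <- 0.03
  trd <- tone_trace(800, zeta = 1 / (2 * pi * 800 * tau), dur = 0.3)
  envd <- mode_power_envelope(bandpass_mode(trd, c(600, 1000)))
  t <- trace_times(envd)
  sel <- t > 0.02 & t < 0.1
  rate <- -coef(lm(log(envd$samples[sel]) ~ t[sel]))[[2]]
  expect_equal(rate, 2 / tau, tolerance = 0.05)
  # zero trace -> zero envelope
  z <- voltage_trace(numeric(1000), 20000)
  expect_equal(max(mode_power_envelope(z)$samples), 0)
})

test_that("modal energies recover injected partitions and the 1 kHz split", {
  ms <- fx_rat_modes(9)
  f_j <- ms$table$f_j
  # two modes with a 4:1 energy ratio
  tr2 <- generate_texture_sweep(c(400, 2500), event_rate = 1,
                                cfg = ensemble_config(noise_floor = 1e-6,
                                                      seed = 8),
                                duration = 1, event_times = 0.5,
                                partitions = matrix(c(0.8, 0.2), 1),
                                dispersion = "off")
  bank2 <- mode_band_bank(c(400, 2500), f_range = c(50, 9000))
  en2 <- modal_energy(modal_power(tr2, bank2), window = c(0.4, 0.65))
  expect_equal(en2$fraction, c(0.8, 0.2), tolerance = 0.05)
  # single mode -> fraction 1
  tr1 <- generate_texture_sweep(900, event_rate = 1,
                                cfg = ensemble_config(noise_floor = 1e-6,
                                                      seed = 8),
                                duration = 1, event_times = 0.5,
                                partitions = matrix(1, 1),
                                dispersion = "off")
  en1 <- modal_energy(modal_power(tr1, mode_band_bank(900)),
                      window = c(0.4, 0.65))
  expect_equal(en1$fraction, 1)
  # 9-mode event with 79% of energy above 1 kHz
  hi <- f_j > 1000
  frac <- numeric(9)
  frac[hi] <- 0.79 * seq_len(sum(hi)) / sum(seq_len(sum(hi)))
  frac[!hi] <- 0.21 * rev(seq_len(sum(!hi))) / sum(seq_len(sum(!hi)))
  tr9 <- generate_texture_sweep(ms, event_rate = 1,
                                cfg = ensemble_config(noise_floor = 1e-5,
                                                      seed = 5),
                                duration = 1, event_times = 0.5,
                                partitions = matrix(frac, 1),
                                dispersion = "off")
  en9 <- modal_energy(modal_power(tr9, mode_band_bank(ms, c(20, 9000))),
                      window = c(0.38, 0.65))
  expect_equal(en9$split[["above"]], 0.79, tolerance = 0.05)
  expect_lt(max(abs(en9$fraction - frac)), 0.05)
  expect_error(modal_energy(modal_power(tr9, mode_band_bank(ms)),
                            window = c(2, 3)), "window")
})

test_that("complete band partitions conserve total signal energy", {
  # in-band multi-tone signal; gapless gapped bank over the full range
  tr <- generate_slipoff_trace(c(300, 800, 2000), zeta = 0.01,
                               amplitudes = c(1, 0.5, 0.25),
                               cfg = ensemble_config(noise_floor = 0),
                               duration = 0.3, V_off = 0.5)
  bank <- mode_band_bank(c(300, 800, 2000), f_range = c(10, 9999))
  x <- offset_correct(tr)
  total <- sum(x^2) / tr$sample_rate
  mp <- modal_power(tr, bank)
  t <- mp$times
  band_sum <- sum(vapply(1:3, function(k)
    whiskervib:::trapz_num(t, mp$U[, k]) / 2, 0))
  # |analytic|^2 integrates to twice the real-signal energy
  expect_equal(band_sum, total, tolerance = 0.02)
})
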