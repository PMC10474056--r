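# Shared fixtures, built once per test run and cached (several tests reuse
# the same eigenmode tables and spectrograms; solving/transforming once
# keeps the suite fast).

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# rat-whisker-like geometry trimmed to 29 of 40 mm (the simulation
# configuration: E = 2 GPa, rho = 1000 kg/m^3, R_b = 60 um)
fx_rat_geom <- function() {
  whisker_geometry(S_tot = 40, R_b = 60e-3, r_t = 0, l = 29,
                   E = 2e9, rho = 1000, unit = "mm")
}

fx_rat_modes <- function(n = 10) {
  ms <- fx_cache("rat_modes_12",
                 solve_eigenmodes(fx_rat_geom(), n_modes = 12,
                                  grid_size = 300, check = FALSE))
  ms$table <- ms$table[seq_len(n), , drop = FALSE]
  ms
}

# mouse-whisker-like geometry (21.5 mm, E close to the mouse fit value)
fx_mouse_geom <- function() {
  whisker_geometry(S_tot = 21.5, R_b = 33e-3, r_t = 0, l = 21.5,
                   E = 3.9583e9, rho = 1100, unit = "mm")
}

# multi-mode slip-off trace with zeta = 1.5/f (equal decay rates) and its
# spectrogram; onset 0.1 s inside a 0.6 s trace
fx_slipoff <- function() {
  fx_cache("slipoff", {
    ms <- fx_rat_modes(10)
    zeta <- pmin(0.3, 1.5 / ms$table$f_j)
    tr <- generate_slipoff_trace(ms, zeta = zeta, amplitudes = 1,
                                 cfg = ensemble_config(noise_floor = 1e-4,
                                                       seed = 2),
                                 duration = 0.6, t_onset = 0.1)
    sp <- cmw_spectrogram(tr, f_min = 30, f_max = 6000, n_freq = 600)
    list(trace = tr, spect = sp, modes = ms, zeta = zeta, onset = 0.1)
  })
}

# simulated base shear in the standard configuration
fx_sim <- function() {
  fx_cache("sim", {
    geom <- fx_rat_geom()
    ms <- fx_rat_modes(12)
    cfg <- simulator_config(pole_arc_position = 2e-3, alpha = 430,
                            dt = 1e-5, n_points = 30000, n_modes = 12)
    list(geom = geom, modes = ms, cfg = cfg,
         trace = simulate_base_shear(geom, cfg, modes = ms))
  })
}

# three-tooth grating sweep: traced shapes, kinematics and power trace
fx_grating <- function() {
  fx_cache("grating", {
    geom <- whisker_geometry(S_tot = 24.1, R_b = 35e-3, r_t = 2e-3,
                             l = 24.1, E = 3e9, rho = 1100,
                             A_curv = 15e-3, unit = "mm")
    events <- data.frame(pinned_start = c(0.02, 0.05, 0.08),
                         unpinned_start = c(0.032, 0.062, 0.092),
                         collision_time = c(0.036, 0.066, 0.096),
                         kappa_peak = 30, kappa_drop = 26)
    shp <- generate_whisker_shapes(geom, events, duration = 0.11,
                                   frame_rate = 1460,
                                   sweep_rate_deg_s = 200)
    kin <- tip_kinematics(shp$frames)
    kap <- vapply(split(shp$frames, shp$frames$frame), function(f)
      as.numeric(whisker_curvature(f, segment_center = geom$S_tot / 3,
                                   A_curv = geom$A_curv,
                                   S_tot = geom$S_tot)), 0)
    power <- generate_collision_power_trace(events$collision_time,
                                            duration = 0.11,
                                            amplitude = 1,
                                            noise_floor = 1e-3)
    list(geom = geom, events = events, shapes = shp, kin = kin,
         curv = data.frame(time = shp$truth$time, kappa = kap),
         power = power)
  })
}

# deterministic spike ensemble whose two-state words give exactly 1 bit:
# p(1|t) is 1 on half the bins and 0 on the other half
fx_two_state_ensemble <- function(n_trials = 10) {
  spikes <- c(0.5, 1.5, 2.5, 3.5, 4.5) * 1e-3  # odd bins at dt = 0.5 ms
  spike_ensemble(rep(list(spikes), n_trials), t_start = 0, T = 5e-3)
}
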