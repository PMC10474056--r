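#' Ensemble configuration for synthetic trials
#'
#' Trial-to-trial variability of nominally identical sweeps: small timing
#' jitter of the whole trace, multiplicative amplitude scatter, and an
#' additive Gaussian noise floor. Defaults emulate the low-variability
#' regime of repeated sweeps over the same surface feature (PSTH peak
#' jitter well under 100 us).
#'
#' @param n_trials number of trials
#' @param timing_jitter_sd SD of per-trial time shift \[s\]
#' @param amplitude_cv coefficient of variation of the per-trial amplitude
#'   scale (dimensionless)
#' @param noise_floor RMS of the additive Gaussian noise \[V\]
#' @param seed integer root seed; per-trial streams are derived from it by
#'   fixed offsets, so outputs are bit-reproducible
#' @return an `ensemble_config` list
#' @export
ensemble_config <- function(n_trials = 10, timing_jitter_sd = 30e-6,
                            amplitude_cv = 0.02, noise_floor = 1e-3,
                            seed = 1) {
  stopifnot(n_trials >= 1, timing_jitter_sd >= 0, amplitude_cv >= 0,
            noise_floor >= 0)
  structure(list(n_trials = as.integer(n_trials),
                 timing_jitter_sd = timing_jitter_sd,
                 amplitude_cv = amplitude_cv, noise_floor = noise_floor,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# run code with a local RNG state so generators are deterministic per seed
# without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

mode_freqs <- function(modes) {
  if (inherits(modes, "mode_set")) modes$table$f_j else as.numeric(modes)
}

#' Synthetic pole slip-off free-vibration trace
#'
#' Sum of damped modal sinusoids plus offset and noise floor:
#' `V(t) = V_off + sum_j A_j exp(-zeta_j omega_j t) sin(omega_dj t + phi_j)
#' + noise`, with `omega_dj = omega_j sqrt(1 - zeta_j^2)`. Ground truth for
#' every injected parameter is attached, so frequency/damping estimators
#' can be validated by round trip.
#'
#' @param modes a [solve_eigenmodes()] result or a numeric vector of modal
#'   frequencies \[Hz\]
#' @param zeta per-mode damping ratios (recycled)
#' @param amplitudes per-mode amplitudes \[V\] (recycled)
#' @param cfg an [ensemble_config()] (uses `noise_floor` and `seed`)
#' @param duration trace length \[s\]
#' @param sample_rate \[S/s\]
#' @param V_off DC offset \[V\]
#' @param phases per-mode phases \[rad\]; default `pi/2` (cosine onset, as
#'   after release from a static deflection). Use `NA` for random phases.
#' @param t_onset vibration onset time within the trace \[s\]
#' @param rails optional length-2 vector of clipping rails \[V\]
#' @return a [voltage_trace()] with attribute `truth` (data.frame `j`,
#'   `f_j`, `zeta`, `A`, `phase`)
#' @export
generate_slipoff_trace <- function(modes, zeta, amplitudes,
                                   cfg = ensemble_config(),
                                   duration = 0.5, sample_rate = 20000,
                                   V_off = 0, phases = pi / 2, t_onset = 0,
                                   rails = NULL) {
  f <- mode_freqs(modes)
  n_modes <- length(f)
  zeta <- rep_len(zeta, n_modes)
  if (any(zeta < 0)) stop("damping ratios must be nonnegative")
  if (any(zeta >= 1)) stop("modes must be underdamped (zeta < 1)")
  A <- rep_len(amplitudes, n_modes)
  with_local_seed(cfg$seed, {
    phi <- if (length(phases) == 1 && is.na(phases[1]))
      stats::runif(n_modes, 0, 2 * pi) else rep_len(phases, n_modes)
    n <- round(duration * sample_rate)
    t <- (seq_len(n) - 1L) / sample_rate - t_onset
    v <- numeric(n)
    omega <- 2 * pi * f
    for (j in seq_len(n_modes)) {
      od <- omega[j] * sqrt(1 - zeta[j]^2)
      v <- v + ifelse(t >= 0,
                      A[j] * exp(-zeta[j] * omega[j] * pmax(t, 0)) *
                        sin(od * pmax(t, 0) + phi[j]),
                      0)
    }
    v <- v + V_off
    if (cfg$noise_floor > 0) v <- v + stats::rnorm(n, 0, cfg$noise_floor)
    clipped <- FALSE
    if (!is.null(rails)) {
      clipped <- any(v < rails[1]) || any(v > rails[2])
      v <- pmin(pmax(v, rails[1]), rails[2])
    }
    tr <- voltage_trace(v, sample_rate = sample_rate, V_off = V_off,
                        gain_label = "synthetic slip-off", clipped = clipped)
    attr(tr, "truth") <- data.frame(j = seq_len(n_modes), f_j = f,
                                    zeta = zeta, A = A, phase = phi)
    tr
  })
}

#' Synthetic texture-sweep trace: a point process of collision shockwaves
#'
#' Each collision event injects one multi-mode wave packet. Mode `j`
#' contributes a Gaussian-envelope tone centered at its arrival time; with
#' `dispersion = "on"` that arrival is delayed from the collision by
#' `propagation_length / v_g(omega_j)` (flexural-rod group velocity, see
#' [group_velocity()]), so low modes lag high modes as they do on a real
#' whisker. Per-event modal energy fractions come from `partition_sampler`
#' and are stored as ground truth; per-mode amplitudes are set so the
#' integral of the squared tone equals the assigned energy share.
#'
#' The envelope SD of mode `j` is `max(rise_time, min_cycles / f_j)`: a
#' fixed sub-millisecond rise for high modes, widened for low modes so
#' each packet stays inside its own spectral band.
#'
#' @param modes mode frequencies (as in [generate_slipoff_trace()])
#' @param event_rate mean collision rate \[events/s\] (Poisson process)
#' @param cfg an [ensemble_config()]
#' @param duration trace length \[s\]
#' @param sample_rate \[S/s\]
#' @param partition_sampler `function(n_modes)` returning energy fractions
#'   summing to 1; default draws from a symmetric Dirichlet (unit
#'   exponentials, normalized)
#' @param dispersion `"on"` or `"off"`
#' @param geom a [whisker_geometry()]; needed for group velocities when
#'   `dispersion = "on"` (radius `R_b` is used, matching the uniform-rod
#'   dispersion law)
#' @param propagation_length distance from collision site to base \[m\]
#' @param event_energy mean event energy \[V^2 s\]; per-event impulse
#'   magnitudes are lognormal around it (sdlog 0.5)
#' @param rise_time minimum packet envelope SD \[s\]
#' @param min_cycles lower bound on the envelope SD in oscillation periods
#'   (`min_cycles / f_j`); larger values narrow each packet's spectral
#'   footprint, keeping dense high-order modes inside their own bands
#' @param V_off DC offset \[V\]
#' @param event_times optional explicit collision times \[s\], overriding
#'   the Poisson draw
#' @param partitions optional explicit fraction matrix (events x modes)
#' @return a [voltage_trace()] with attribute `event_log`: list with
#'   `events` (data.frame `event`, `pinned_start`, `unpinned_start`,
#'   `collision_time`, `impulse`, `overlaps`) and `fractions`
#'   (events x modes matrix), `arrival_delays` \[s\] per mode, and
#'   `envelope_sd` per mode
#' @export
generate_texture_sweep <- function(modes, event_rate, cfg = ensemble_config(),
                                   duration = 1, sample_rate = 20000,
                                   partition_sampler = NULL,
                                   dispersion = c("on", "off"),
                                   geom = NULL, propagation_length = 0,
                                   event_energy = 1e-4, rise_time = 0.5e-3,
                                   min_cycles = 1.5, V_off = 0,
                                   event_times = NULL, partitions = NULL) {
  dispersion <- match.arg(dispersion)
  f <- mode_freqs(modes)
  n_modes <- length(f)
  stopifnot(event_rate > 0, event_rate < sample_rate / 100)
  if (dispersion == "on" && propagation_length > 0 && is.null(geom))
    stop("dispersion requires a whisker_geometry for the group velocities")
  if (is.null(partition_sampler))
    partition_sampler <- function(m) { e <- stats::rexp(m); e / sum(e) }
  delays <- if (dispersion == "on" && propagation_length > 0)
    propagation_length / group_velocity(geom$E, geom$R_b, geom$rho, 2 * pi * f)
  else rep(0, n_modes)
  sd_j <- pmax(rise_time, min_cycles / f)
  with_local_seed(cfg$seed, {
    if (is.null(event_times)) {
      n_ev <- stats::rpois(1, event_rate * duration * 0.8)
      event_times <- sort(stats::runif(n_ev, 0.05 * duration, 0.85 * duration))
    }
    n_ev <- length(event_times)
    n <- round(duration * sample_rate)
    t <- (seq_len(n) - 1L) / sample_rate
    v <- numeric(n)
    if (is.null(partitions) && n_ev > 0) {
      partitions <- t(vapply(seq_len(n_ev), function(i) {
        p <- partition_sampler(n_modes)
        if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
          stop("partition_sampler must return nonnegative fractions summing to 1")
        p
      }, numeric(n_modes)))
    }
    impulse <- if (n_ev > 0)
      event_energy * stats::rlnorm(n_ev, 0, 0.5) else numeric(0)
    phases <- if (n_ev > 0)
      matrix(stats::runif(n_ev * n_modes, 0, 2 * pi), n_ev) else NULL
    for (i in seq_len(n_ev)) {
      for (j in seq_len(n_modes)) {
        e_j <- impulse[i] * partitions[i, j]
        if (e_j <= 0) next
        t_arr <- event_times[i] + delays[j]
        # integral of (A g sin)^2 dt ~ A^2 sd sqrt(pi) / 2 for a Gaussian g
        A_j <- sqrt(2 * e_j / (sd_j[j] * sqrt(pi)))
        sel <- which(abs(t - t_arr) < 5 * sd_j[j])
        if (!length(sel)) next
        v[sel] <- v[sel] + A_j * exp(-(t[sel] - t_arr)^2 / (2 * sd_j[j]^2)) *
          sin(2 * pi * f[j] * (t[sel] - t_arr) + phases[i, j])
      }
    }
    v <- v + V_off
    if (cfg$noise_floor > 0) v <- v + stats::rnorm(n, 0, cfg$noise_floor)
    tr <- voltage_trace(v, sample_rate = sample_rate, V_off = V_off,
                        gain_label = "synthetic texture sweep")
    span <- max(delays) + 5 * max(sd_j)
    overlaps <- if (n_ev > 1)
      c(diff(event_times) < span, FALSE) | c(FALSE, diff(event_times) < span)
    else rep(FALSE, n_ev)
    events <- data.frame(event = seq_len(n_ev),
                         pinned_start = event_times - 15e-3,
                         unpinned_start = event_times - 4e-3,
                         collision_time = event_times,
                         impulse = impulse, overlaps = overlaps)
    attr(tr, "event_log") <- list(events = events, fractions = partitions,
                                  arrival_delays = delays, envelope_sd = sd_j,
                                  mode_freqs = f)
    tr
  })
}

#' Trial ensemble of nominally identical traces
#'
#' Replicates a noise-free base trace `n_trials` times with per-trial time
#' jitter (Gaussian, SD `timing_jitter_sd`, applied by linear-interpolation
#' resampling), multiplicative amplitude scale (`1 + amplitude_cv * z`),
#' and fresh additive noise. All randomness derives from `cfg$seed` through
#' fixed per-trial offsets, so the ensemble is reproducible bit-exactly.
#'
#' @param base_trace a [voltage_trace()]; its `V_off` is preserved, jitter
#'   and scaling act on the offset-corrected signal
#' @param cfg an [ensemble_config()]
#' @return list of [voltage_trace()] with attribute `truth` (data.frame
#'   `trial`, `jitter`, `scale`)
#' @export
generate_trial_ensemble <- function(base_trace, cfg = ensemble_config()) {
  stopifnot(inherits(base_trace, "voltage_trace"), cfg$n_trials >= 1)
  v0 <- offset_correct(base_trace)
  t <- trace_times(base_trace)
  with_local_seed(cfg$seed, {
    jit <- stats::rnorm(cfg$n_trials, 0, cfg$timing_jitter_sd)
    scl <- 1 + cfg$amplitude_cv * stats::rnorm(cfg$n_trials)
    trials <- vector("list", cfg$n_trials)
    for (i in seq_len(cfg$n_trials)) {
      vi <- if (jit[i] != 0)
        stats::approx(t, v0, xout = t - jit[i], rule = 2)$y else v0
      vi <- scl[i] * vi + base_trace$V_off
      if (cfg$noise_floor > 0)
        vi <- vi + stats::rnorm(length(vi), 0, cfg$noise_floor)
      trials[[i]] <- voltage_trace(vi, sample_rate = base_trace$sample_rate,
                                   V_off = base_trace$V_off,
                                   t0 = base_trace$t0,
                                   gain_label = sprintf("trial %d", i))
    }
    attr(trials, "truth") <- data.frame(trial = seq_len(cfg$n_trials),
                                        jitter = jit, scale = scl)
    trials
  })
}

# arc-length parameterization of the intrinsic parabola y = A x^2:
# returns curvature and coordinates at arc lengths s (from the apex)
intrinsic_parabola <- function(A_curv, s_max, n = 2000) {
  if (A_curv == 0) {
    return(list(x = function(s) s, y = function(s) 0 * s,
                kappa = function(s) 0 * s, psi = function(s) 0 * s))
  }
  xg <- seq(0, 2 * s_max, length.out = n)
  dsdx <- sqrt(1 + (2 * A_curv * xg)^2)
  sg <- cumtrapz_num(xg, dsdx)
  x_of_s <- stats::approxfun(sg, xg, rule = 2)
  list(x = x_of_s,
       y = function(s) A_curv * x_of_s(s)^2,
       kappa = function(s) {
         x <- x_of_s(s); 2 * A_curv / (1 + (2 * A_curv * x)^2)^1.5
       },
       psi = function(s) atan(2 * A_curv * x_of_s(s)))
}

#' Intrinsic curvature of the undeformed whisker at an arc-length position
#'
#' Curvature of the parabola `A_curv * x^2` evaluated at arc length `s`
#' from the base (apex). Subtracted by [whisker_curvature()] so that the
#' reported bending curvature is contact-induced only.
#'
#' @param A_curv parabolic coefficient \[1/m\]
#' @param s arc length from the base \[m\]
#' @return curvature \[1/m\]
#' @export
intrinsic_curvature <- function(A_curv, s) {
  if (A_curv == 0) return(0 * s)
  intrinsic_parabola(A_curv, max(s) + 1e-6)$kappa(s)
}

cumtrapz_num <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# C2-smooth quintic step: s(0)=0, s(1)=1, zero first and second
# derivatives at both ends; peak second derivative 5.772/d^2 inside
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# closed-form kinematic state of the synthetic sweep at arbitrary times:
# bending curvature amplitude kappa(t) and the contact-angle deviation
# phi_dev(t) [deg] from the uniform sweep. The contact angle is frozen
# during the pinned phase, released by half the held-back angle through a
# smooth quintic step over the unpinned phase (interior acceleration peak
# 5.772 * (held/2) / d^2), and relaxes exponentially after the collision
# (the velocity kink at the collision is the deceleration transient).
sweep_state <- function(time, events, sweep_rate_deg_s, relax_tau = 10e-3) {
  kappa <- numeric(length(time))
  phi_dev <- numeric(length(time))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    ramp <- ev$kappa_peak / (ev$unpinned_start - ev$pinned_start)
    drop_d <- ev$collision_time - ev$unpinned_start
    held <- sweep_rate_deg_s * (ev$unpinned_start - ev$pinned_start)
    def <- sweep_rate_deg_s * (ev$collision_time - ev$pinned_start) - held / 2
    for (k in seq_along(time)) {
      tt <- time[k]
      if (tt >= ev$pinned_start && tt < ev$unpinned_start) {
        kappa[k] <- kappa[k] + ramp * (tt - ev$pinned_start)
        phi_dev[k] <- phi_dev[k] - sweep_rate_deg_s * (tt - ev$pinned_start)
      } else if (tt >= ev$unpinned_start && tt < ev$collision_time) {
        x <- smoothstep((tt - ev$unpinned_start) / drop_d)
        kappa[k] <- kappa[k] + ev$kappa_peak - ev$kappa_drop * x
        phi_dev[k] <- phi_dev[k] -
          sweep_rate_deg_s * (tt - ev$pinned_start) + (held / 2) * x
      } else if (tt >= ev$collision_time) {
        rel <- exp(-(tt - ev$collision_time) / relax_tau)
        kappa[k] <- kappa[k] + (ev$kappa_peak - ev$kappa_drop) * rel
        phi_dev[k] <- phi_dev[k] - def * rel
      }
    }
  }
  list(kappa = kappa, phi_deg = sweep_rate_deg_s * time + phi_dev)
}

#' Synthetic traced whisker shapes through pinned-unpinned-collision events
#'
#' Emulates the per-frame coordinate tables produced by tracing a high-speed
#' video of a whisker sweeping across a grating. The whisker shape is built
#' from its tangent-angle integral: intrinsic parabolic curvature plus a
#' contact-induced bending term `kappa_b(t) * b(s)` localized in a Gaussian
#' bump (`bump_sd`) around the curvature evaluation point. During each
#' event `kappa_b` ramps linearly through the pinned phase, drops by
#' `kappa_drop` over the unpinned phase (smooth quintic step), and relaxes
#' after the collision.
#'
#' The whole-frame rotation is chosen so the contact angle follows the
#' pinned-unpinned-collision profile exactly: frozen while pinned (the tip
#' is stuck on the tooth), released through the quintic step (interior
#' acceleration peak `5.772 * release / d^2`, with `release` half the
#' held-back angle and `d` the unpinned duration), then relaxing toward
#' the uniform sweep; the velocity kink at the collision is the
#' deceleration transient. Because a rigid rotation adds the same angle to
#' every traced point, the generator enforces this exactly by compensating
#' the bending-induced tip rotation, and the ground-truth contact angle is
#' closed form; velocity and acceleration truth come from differencing it
#' on a 10x finer time grid.
#'
#' @param geom a [whisker_geometry()]
#' @param events data.frame with columns `pinned_start`, `unpinned_start`,
#'   `collision_time` \[s\], `kappa_peak`, `kappa_drop` \[1/m\]
#' @param duration recording length \[s\]
#' @param frame_rate \[frames/s\]
#' @param sweep_rate_deg_s base angular sweep velocity \[deg/s\]
#' @param span traced arc-length interval `c(from, to)` \[m\] (default 2 mm
#'   from the base to 3 mm from the tip)
#' @param ds arc-length sampling step \[m\]
#' @param bump_s arc-length center of the bending bump \[m\] (default one
#'   third of the arc length, the curvature evaluation point)
#' @param bump_sd SD of the bending bump \[m\]
#' @return list with `frames` (data.frame `frame`, `time`, `s`, `x`, `y`),
#'   `truth` (data.frame per frame: `time`, `kappa_p` bending curvature at
#'   `bump_s`, `theta_deg` frame rotation, `contact_angle_deg`,
#'   `contact_velocity_deg_s`, `contact_accel_deg_s2`), and `params`
#'   (generator parameters, including per-event `unpin_accel_peak_deg_s2`,
#'   the closed-form interior acceleration peak of the unpinned release)
#' @export
generate_whisker_shapes <- function(geom, events, duration,
                                    frame_rate = 1460,
                                    sweep_rate_deg_s = 200,
                                    span = c(2e-3, geom$l - 3e-3),
                                    ds = 1e-4,
                                    bump_s = geom$S_tot / 3,
                                    bump_sd = 4e-3) {
  stopifnot(frame_rate > 0, all(events$pinned_start < events$unpinned_start),
            all(events$unpinned_start < events$collision_time))
  s <- seq(span[1], span[2], by = ds)
  par_int <- intrinsic_parabola(geom$A_curv, span[2])
  psi_int <- par_int$psi(s)
  bump_cum <- stats::pnorm(s, bump_s, bump_sd) * bump_sd * sqrt(2 * pi)
  x0 <- if (geom$A_curv == 0) span[1] else par_int$x(span[1])
  y0 <- par_int$y(span[1])
  shape_at <- function(kappa_b, theta_deg) {
    psi <- psi_int + kappa_b * bump_cum  # kappa_b * integral of unit-peak bump
    th <- theta_deg * pi / 180
    x <- cumtrapz_num(s, cos(psi + th)) + x0 * cos(th) - y0 * sin(th)
    y <- cumtrapz_num(s, sin(psi + th)) + x0 * sin(th) + y0 * cos(th)
    cbind(x, y)
  }
  # bending-induced contact angle at zero frame rotation, as a function of
  # kappa_b (rigid rotation adds theta to every polar angle exactly, so
  # contact_angle(kappa, theta) = eta(kappa) + theta)
  eta_of <- function(kappa_b) {
    xy <- shape_at(kappa_b, 0)
    sel <- s >= (span[2] - 0.5e-3)
    atan2(mean(xy[sel, 2]), mean(xy[sel, 1])) * 180 / pi
  }
  k_lo <- min(0, min(events$kappa_peak) - max(events$kappa_drop))
  k_hi <- max(max(events$kappa_peak) * 1.05, k_lo + 1)
  kg <- seq(k_lo, k_hi, length.out = 200)
  eta_fun <- stats::approxfun(kg, vapply(kg, eta_of, 0), rule = 2)
  n_frames <- floor(duration * frame_rate)
  t_frames <- (seq_len(n_frames) - 1L) / frame_rate
  st <- sweep_state(t_frames, events, sweep_rate_deg_s)
  theta_frames <- st$phi_deg - eta_fun(st$kappa)
  frames <- do.call(rbind, lapply(seq_len(n_frames), function(i) {
    xy <- shape_at(st$kappa[i], theta_frames[i])
    data.frame(frame = i, time = t_frames[i], s = s,
               x = xy[, 1], y = xy[, 2])
  }))
  # contact-angle truth is closed form; differentiate it on a 10x finer grid
  dtf <- 1 / (10 * frame_rate)
  t_fine <- seq(0, max(t_frames), by = dtf)
  ang_fine <- sweep_state(t_fine, events, sweep_rate_deg_s)$phi_deg
  vel_fine <- c(NA, diff(ang_fine, lag = 2) / (2 * dtf), NA)
  acc_fine <- c(NA, diff(ang_fine, differences = 2) / dtf^2, NA)
  idx <- round(t_frames / dtf) + 1L
  truth <- data.frame(
    frame = seq_len(n_frames), time = t_frames,
    kappa_p = st$kappa, theta_deg = theta_frames,
    contact_angle_deg = st$phi_deg,
    contact_velocity_deg_s = vel_fine[idx],
    contact_accel_deg_s2 = acc_fine[idx])
  held <- sweep_rate_deg_s * (events$unpinned_start - events$pinned_start)
  dd <- events$collision_time - events$unpinned_start
  list(frames = frames, truth = truth,
       params = list(span = span, ds = ds, bump_s = bump_s,
                     bump_sd = bump_sd, sweep_rate_deg_s = sweep_rate_deg_s,
                     frame_rate = frame_rate, events = events,
                     unpin_accel_peak_deg_s2 = 5.7735 * (held / 2) / dd^2))
}

#' Synthetic broadband power transients aligned to collisions
#'
#' Companion trace for [segment_phases()] fixtures: the squared
#' offset-corrected microphone power shows a sharp transient at each
#' collision. Each transient has an abrupt (0.2 ms SD) Gaussian-edged onset
#' and exponential 5 ms decay above a noise floor.
#'
#' @param collision_times collision times \[s\]
#' @param duration trace length \[s\]
#' @param sample_rate \[S/s\]
#' @param amplitude transient peak power \[V^2\]
#' @param noise_floor mean power of the noise background \[V^2\]
#' @param seed RNG seed for the background
#' @return a [voltage_trace()] in units `"V^2"`
#' @export
generate_collision_power_trace <- function(collision_times, duration,
                                           sample_rate = 20000,
                                           amplitude = 1, noise_floor = 1e-3,
                                           seed = 1) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  p <- numeric(n)
  for (tc in collision_times) {
    up <- t >= tc
    p[up] <- p[up] + amplitude * exp(-(t[up] - tc) / 5e-3)
  }
  with_local_seed(seed, {
    p <- p + noise_floor * (stats::rchisq(n, df = 2) / 2)
  })
  voltage_trace(p, sample_rate = sample_rate, V_off = 0, units = "V^2",
                gain_label = "synthetic broadband power")
}
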