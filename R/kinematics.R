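#' Local whisker curvature from a traced shape frame
#'
#' Fits a second-order polynomial to a whisker segment (default 2 mm wide,
#' centered at one third of the total arc length) in the segment's own
#' tangent frame, and reports the curvature of the fit at the segment
#' center with the intrinsic (undeformed-parabola) curvature subtracted,
#' so the result is the contact-induced bending curvature.
#'
#' Rotating into the tangent frame first keeps the quadratic fit valid for
#' strongly bent shapes, where the lab-frame slope would be far from
#' small.
#'
#' @param frame data.frame with columns `s` (arc length from base \[m\],
#'   strictly increasing), `x`, `y` \[m\] for one video frame
#' @param segment_center evaluation point as arc length \[m\]; default one
#'   third of `S_tot`
#' @param segment_width segment width \[m\]
#' @param A_curv intrinsic parabolic coefficient \[1/m\] to subtract
#'   (0 = no subtraction)
#' @param S_tot total arc length \[m\], used only for the default center
#' @return curvature \[1/m\] with attribute `low_confidence` (TRUE when the
#'   segment is collinear to numerical precision, in which case 0 is
#'   returned)
#' @export
whisker_curvature <- function(frame, segment_center = S_tot / 3,
                              segment_width = 2e-3, A_curv = 0,
                              S_tot = max(frame$s)) {
  stopifnot(all(c("s", "x", "y") %in% names(frame)),
            all(diff(frame$s) > 0))
  half <- segment_width / 2
  if (segment_center - half < min(frame$s) ||
      segment_center + half > max(frame$s))
    stop("curvature segment extends outside the traced span")
  sel <- frame$s >= segment_center - half & frame$s <= segment_center + half
  if (sum(sel) < 5) stop("fewer than 5 traced points in the segment")
  xs <- frame$x[sel]; ys <- frame$y[sel]
  # rotate into the segment's tangent frame
  th <- atan2(ys[length(ys)] - ys[1], xs[length(xs)] - xs[1])
  u <- (xs - mean(xs)) * cos(th) + (ys - mean(ys)) * sin(th)
  v <- -(xs - mean(xs)) * sin(th) + (ys - mean(ys)) * cos(th)
  fit <- stats::lm(v ~ u + I(u^2))
  c2 <- stats::coef(fit)[[3]]; c1 <- stats::coef(fit)[[2]]
  if (!is.finite(c2) || sd(v) < 1e-12 * max(diff(range(u)), 1e-300)) {
    return(structure(0, low_confidence = TRUE))
  }
  u0 <- (segment_center - mean(frame$s[sel]))  # eval point in tangent frame
  slope <- c1 + 2 * c2 * u0
  kappa <- 2 * c2 / (1 + slope^2)^1.5
  structure(kappa - intrinsic_curvature(A_curv, segment_center),
            low_confidence = FALSE)
}

#' Contact-angle kinematics of the whisker tip across frames
#'
#' The contact angle of each frame is the polar angle of the mean position
#' of the outermost `segment` of the traced span (the 0.5 mm of whisker
#' next to the contact point). Angular velocity and acceleration follow by
#' central differences on the (possibly nonuniform) timestamps.
#'
#' @param frames data.frame with columns `frame`, `time` \[s\], `s`, `x`,
#'   `y` \[m\] (concatenated shape frames, e.g.
#'   `generate_whisker_shapes()$frames`)
#' @param segment length of the tip segment \[m\]
#' @return data.frame of class `kinematics_trace`: `frame`, `time`,
#'   `angle_deg`, `velocity_deg_s`, `accel_deg_s2` (endpoints `NA`)
#' @export
tip_kinematics <- function(frames, segment = 0.5e-3) {
  stopifnot(all(c("frame", "time", "s", "x", "y") %in% names(frames)))
  sp <- split(frames, frames$frame)
  tm <- vapply(sp, function(f) f$time[1], 0)
  ord <- order(tm)
  sp <- sp[ord]; tm <- tm[ord]
  if (length(sp) < 3) stop("need at least 3 frames for kinematics")
  if (any(diff(tm) <= 0)) stop("frame timestamps must be strictly increasing")
  ang <- vapply(sp, function(f) {
    sel <- f$s >= max(f$s) - segment
    atan2(mean(f$y[sel]), mean(f$x[sel])) * 180 / pi
  }, 0)
  ang <- unwrap_deg(ang)
  n <- length(ang)
  vel <- acc <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    h1 <- tm[i] - tm[i - 1]; h2 <- tm[i + 1] - tm[i]
    vel[i] <- (ang[i + 1] - ang[i - 1]) / (h1 + h2)
    acc[i] <- 2 * (h1 * ang[i + 1] - (h1 + h2) * ang[i] + h2 * ang[i - 1]) /
      (h1 * h2 * (h1 + h2))
  }
  out <- data.frame(frame = as.integer(names(sp)), time = tm,
                    angle_deg = ang, velocity_deg_s = vel,
                    accel_deg_s2 = acc)
  class(out) <- c("kinematics_trace", "data.frame")
  out
}

unwrap_deg <- function(a) {
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  c(a[1], a[1] + cumsum(d))
}

#' Segment pinned / unpinned / collision phases
#'
#' Event segmentation combining the traced kinematics with the
#' time-synchronized broadband power trace:
#' \itemize{
#'   \item collision: onset of a power transient (first upward crossing of
#'     `power_mult` times the robust noise floor, transients closer than
#'     `refractory` merged);
#'   \item unpinned start: beginning of the fast curvature drop preceding
#'     the collision (last time curvature still rises within the lookback
#'     window), which coincides with the tip acceleration peak;
#'   \item pinned start: start of the monotone curvature ramp before the
#'     unpinned transition, with sub-threshold tip speed.
#' }
#' Events whose three timestamps do not come out strictly ordered are
#' discarded with a warning.
#'
#' @param kin a [tip_kinematics()] result
#' @param curvature data.frame with `time` \[s\] and `kappa` \[1/m\] (e.g.
#'   per-frame [whisker_curvature()] values)
#' @param power a broadband power [voltage_trace()] (squared
#'   offset-corrected voltage), time-aligned with the frames
#' @param power_mult collision threshold as a multiple of the robust noise
#'   floor (median of the power trace)
#' @param lookback how far before a collision to search for the unpinned
#'   transition \[s\]
#' @param speed_max maximum tip speed during the pinned phase \[deg/s\]
#' @param refractory minimum separation between collision onsets \[s\]
#' @param drop_rate curvature decrease rate marking the unpinned fast drop
#'   \[1/m/s\]
#' @param rise_rate curvature increase rate marking the pinned ramp
#'   \[1/m/s\]
#' @return data.frame: `event`, `pinned_start`, `unpinned_start`,
#'   `collision_time` \[s\]
#' @export
segment_phases <- function(kin, curvature, power, power_mult = 10,
                           lookback = 40e-3, speed_max = 50,
                           refractory = 15e-3, drop_rate = 500,
                           rise_rate = 200) {
  pt <- trace_times(power)
  p <- power$samples
  floor_p <- stats::median(p)
  thr <- power_mult * floor_p
  up <- which(p[-1] >= thr & p[-length(p)] < thr) + 1L
  if (length(up)) {
    keep <- c(TRUE, diff(pt[up]) > refractory)
    up <- up[keep]
  }
  ct <- curvature$time
  rate <- c(NA, diff(curvature$kappa) / diff(ct))  # rate[i]: into frame i
  events <- list()
  for (ci in seq_along(up)) {
    t_col <- pt[up[ci]]
    w <- which(ct >= t_col - lookback & ct <= t_col + 1e-9)
    if (length(w) < 3) next
    # last contiguous run of fast curvature drop before the collision
    steep <- which(rate[w] < -drop_rate)
    if (!length(steep)) {
      warning(sprintf(
        "discarding power transient at %.4g s: no curvature drop", t_col))
      next
    }
    runs <- split(steep, cumsum(c(1, diff(steep) > 2)))
    run <- runs[[length(runs)]]
    t_unpin <- ct[w[run[1]] - 1L]    # frame where the drop begins
    # contiguous slow-tip curvature ramp ending at the unpinned transition
    before <- which(ct < t_unpin - 1e-9)
    if (!length(before)) next
    i <- max(before)
    t_pin <- NA_real_
    while (i > 1) {
      rising <- !is.na(rate[i]) && rate[i] > rise_rate
      ki <- which.min(abs(kin$time - ct[i]))
      slow <- is.na(kin$velocity_deg_s[ki]) ||
        abs(kin$velocity_deg_s[ki]) < speed_max
      if (!rising || !slow) break
      t_pin <- ct[i - 1L]
      i <- i - 1L
    }
    if (!is.na(t_pin) && t_pin < t_unpin && t_unpin < t_col) {
      events[[length(events) + 1L]] <-
        data.frame(pinned_start = t_pin, unpinned_start = t_unpin,
                   collision_time = t_col)
    } else {
      warning(sprintf("discarding event at %.4g s: phases out of order", t_col))
    }
  }
  if (!length(events))
    return(data.frame(event = integer(), pinned_start = numeric(),
                      unpinned_start = numeric(), collision_time = numeric()))
  out <- do.call(rbind, events)
  cbind(event = seq_len(nrow(out)), out)
}

#' Contact force from curvature
#'
#' `F_p = kappa_p E I_p / (r_p cos(theta_p - theta_contact))` with
#' `I_p = pi a_p^4 / 4`: the quasi-static force at the contact inferred
#' from the bending curvature at evaluation point `p`.
#'
#' @param kappa_p bending curvature at `p` \[1/m\]
#' @param geom a [whisker_geometry()] (supplies `E`)
#' @param a_p whisker radius at `p` \[m\]
#' @param r_p arm of the force at `p` \[m\]
#' @param theta_p angle of the vector from `p` to the contact site \[rad\]
#' @param theta_contact whisker angle at the contact \[rad\]
#' @return force \[N\]
#' @export
contact_force <- function(kappa_p, geom, a_p, r_p, theta_p, theta_contact) {
  stopifnot(r_p > 0, a_p > 0)
  dth <- theta_p - theta_contact
  if (abs(cos(dth)) < 1e-9)
    stop("geometry singular: force direction perpendicular to the arm")
  if (abs(dth) >= pi / 2)
    stop("angle between force and arm must be below pi/2")
  I_p <- pi * a_p^4 / 4
  kappa_p * geom$E * I_p / (r_p * cos(dth))
}

#' Elastic strain energy stored in the bent whisker
#'
#' `U = (pi / 24) kappa_p^2 S_tot^3 E a_p^4 / (r_p^2 cos^2(theta_p -
#' theta_contact))`, equal to the cantilever strain energy
#' `F^2 S_tot^3 / (6 E I)` with the contact force of [contact_force()] and
#' the area moment evaluated at the same point `p` (the two routes agree
#' identically under that shared convention).
#'
#' @inheritParams contact_force
#' @return energy \[J\]
#' @export
strain_energy <- function(kappa_p, geom, a_p, r_p, theta_p, theta_contact) {
  F_p <- contact_force(kappa_p, geom, a_p, r_p, theta_p, theta_contact)
  I_p <- pi * a_p^4 / 4
  F_p^2 * geom$S_tot^3 / (6 * geom$E * I_p)
}

#' Rotational impact energy
#'
#' Upper bound of the energy released at the collision: the rotational
#' kinetic energy `K = I_rot omega_rot^2 / 2` of the whisker at the moment
#' of impact. `I_rot` is the mass moment of inertia about the base
#' \[kg m^2\] -- distinct from the area moment `I_p` \[m^4\] of
#' [contact_force()]. If `I_rot` is not supplied it is computed from the
#' geometry as `integral rho pi r(s)^2 s^2 ds` over the truncated whisker.
#'
#' @param omega_rot rotational velocity at collision \[rad/s\]
#' @param I_rot mass moment of inertia \[kg m^2\]
#' @param geom a [whisker_geometry()] (used when `I_rot` is missing)
#' @return kinetic energy \[J\]
#' @export
rotational_impact_energy <- function(omega_rot, I_rot = NULL, geom = NULL) {
  stopifnot(omega_rot >= 0)
  if (is.null(I_rot)) {
    if (is.null(geom)) stop("supply I_rot or geom")
    I_rot <- rotational_inertia(geom)
  }
  stopifnot(I_rot >= 0)
  I_rot * omega_rot^2 / 2
}

#' @rdname rotational_impact_energy
#' @export
rotational_inertia <- function(geom) {
  s <- seq(0, geom$l, length.out = 2000)
  trapz_num(s, geom$rho * whisker_area(geom, s) * s^2)
}

#' Power reflection coefficient at an impedance step
#'
#' `R = ((Z2 - Z1) / (Z2 + Z1))^2`; symmetric in its arguments. Quantifies
#' how much vibrational power reflects at the base (keratin against the
#' metallic microphone, or against follicle tissue) and at the tip
#' (keratin against air).
#'
#' @param Z1,Z2 specific acoustic impedances \[Rayl\], > 0
#' @return power reflection coefficient in `[0, 1)`
#' @export
power_reflection <- function(Z1, Z2) {
  stopifnot(all(Z1 > 0), all(Z2 > 0))
  ((Z2 - Z1) / (Z2 + Z1))^2
}

#' Attenuate an energy by a decibel loss
#'
#' `energy * 10^(-loss_db / 10)`.
#'
#' @param energy energy \[J\] (any nonnegative unit)
#' @param loss_db attenuation \[dB\], >= 0
#' @return attenuated energy, same units
#' @export
attenuate_db <- function(energy, loss_db) {
  stopifnot(all(loss_db >= 0))
  energy * 10^(-loss_db / 10)
}
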