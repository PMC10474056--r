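#' Eigenmodes of a truncated conical fixed-free whisker
#'
#' Solves the transverse eigenproblem of a linearly tapered, truncated,
#' clamped-free Euler-Bernoulli beam,
#' \deqn{(E I(s) w'')'' = \rho A(s) \omega^2 w, \quad w(0)=w'(0)=0,}
#' with free-end conditions at the cut tip `s = l`. Radius tapers linearly,
#' `r(s) = R_b - slope_R * s`, so `A(s) = pi r^2` and `I(s) = pi r^4 / 4`.
#'
#' The operator is discretized by a Rayleigh-Ritz finite-difference scheme:
#' the strain energy `integral EI (w'')^2 ds` and kinetic energy
#' `integral rho A w^2 ds` are evaluated on a uniform grid (second-difference
#' curvature, trapezoidal quadrature) under the clamped constraints, and the
#' resulting generalized symmetric eigenproblem `K w = omega^2 M w` is solved
#' through a Cholesky reduction. Free-end boundary conditions are natural in
#' this variational form, which keeps the scheme robust for strongly tapered
#' (near-zero tip radius) geometries where strong-form difference stencils
#' at the free end become ill-conditioned.
#'
#' Natural frequencies are reported together with the dimensionless
#' coefficients of the standard tapered-beam frequency law
#' \deqn{f_j = \frac{R_b}{4\pi l S_{tot}} \sqrt{E/\rho}\, \gamma_j
#'         = \frac{R_b}{4\pi S_{tot}^2} \sqrt{E/\rho}\, \beta_j,}
#' i.e. `beta_j` is back-computed from `f_j` (and `gamma_j = beta_j * l /
#' S_tot`). For a cylinder, `sqrt(beta_j)` equals the classical cantilever
#' roots 1.8751, 4.6941, ...
#'
#' @param geom a [whisker_geometry()]
#' @param n_modes number of modes to return (<= 30)
#' @param grid_size number of grid intervals along `[0, l]`
#' @param check if `TRUE` (default), certify convergence by re-solving on a
#'   doubled grid and erroring if any returned frequency changes by more
#'   than `tol` (relative)
#' @param tol relative convergence tolerance for the grid-doubling check
#' @return An object of class `mode_set`: list with `table` (data.frame:
#'   `j`, `f_j` \[Hz\], `omega_j` \[rad/s\], `beta_j`, `gamma_j`), `s` (grid,
#'   from base), `shapes` (matrix, columns are mass-normalized mode shapes
#'   on `s`), and `geom`.
#' @examples
#' geom <- whisker_geometry(40, 60e-3, 0, l = 29, E = 2e9, rho = 1000,
#'                          unit = "mm")
#' ms <- solve_eigenmodes(geom, n_modes = 6, grid_size = 300)
#' ms$table$f_j
#' @export
solve_eigenmodes <- function(geom, n_modes = 20, grid_size = 400,
                             check = TRUE, tol = 1e-3) {
  stopifnot(inherits(geom, "whisker_geometry"), n_modes >= 1, n_modes <= 30,
            grid_size >= 10 * n_modes)
  sol <- beam_eigen(geom, n_modes, grid_size)
  if (check) {
    sol2 <- beam_eigen(geom, n_modes, 2L * grid_size)
    rel <- max(abs(sol2$omega - sol$omega) / sol2$omega)
    if (rel > tol)
      stop(sprintf(paste0("eigensolve not converged: frequencies change by ",
                          "%.2g on grid doubling (tol %.2g); increase grid_size"),
                   rel, tol))
  }
  f <- sol$omega / (2 * pi)
  beta <- f / (geom$R_b / (4 * pi * geom$S_tot^2) * sqrt(geom$E / geom$rho))
  out <- list(
    table = data.frame(j = seq_len(n_modes), f_j = f, omega_j = sol$omega,
                       beta_j = beta, gamma_j = beta * geom$l / geom$S_tot),
    s = sol$s, shapes = sol$shapes, geom = geom)
  class(out) <- "mode_set"
  out
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d modes of a %.3g mm whisker (l/S_tot = %.3g)\n",
              nrow(x$table), x$geom$S_tot * 1e3, x$geom$l / x$geom$S_tot))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Discretization shared by the eigensolver and the static solver.
# Unknowns are w at s = h, 2h, ..., l (the base value w(0) = 0 is eliminated;
# w'(0) = 0 enters through the one-sided curvature stencil at the base).
beam_operators <- function(geom, N) {
  h <- geom$l / N
  s <- seq(0, geom$l, length.out = N + 1)
  EI <- whisker_moment(geom, s) * geom$E
  rhoA <- geom$rho * whisker_area(geom, s)
  # curvature rows at nodes 0 .. N-1 (natural BCs at the free end)
  B <- matrix(0, N, N)
  B[1, 1] <- 2 / h^2                       # w''(0) ~ 2 w_1 / h^2 (w(0)=w'(0)=0)
  B[2, 1] <- -2 / h^2; B[2, 2] <- 1 / h^2  # node 1, with w_0 = 0
  if (N > 2) for (i in 2:(N - 1)) {
    B[i + 1, (i - 1):(i + 1)] <- c(1, -2, 1) / h^2
  }
  wq <- rep(h, N); wq[1] <- h / 2          # quadrature weights, nodes 0..N-1
  K <- crossprod(B, B * (EI[1:N] * wq))
  mw <- rep(h, N); mw[N] <- h / 2
  M <- rhoA[2:(N + 1)] * mw                # diagonal mass, nodes 1..N
  list(h = h, s = s, K = (K + t(K)) / 2, M = M, EI0 = EI[1])
}

beam_eigen <- function(geom, n_modes, N) {
  op <- beam_operators(geom, N)
  R <- chol(op$K)
  # R^{-T} diag(sqrt(M)) ; A = R^{-T} M R^{-1} is symmetric PSD with
  # eigenvalues 1/omega^2 (zero-mass tip nodes are harmless here)
  Mi <- backsolve(R, diag(sqrt(op$M)), transpose = TRUE)
  A <- tcrossprod(Mi)
  ev <- eigen(A, symmetric = TRUE)
  mu <- ev$values[seq_len(n_modes)]
  if (any(mu <= 0)) stop("eigensolve failed: nonpositive eigenvalues")
  omega <- 1 / sqrt(mu)
  phi <- backsolve(R, ev$vectors[, seq_len(n_modes), drop = FALSE])
  # mass-normalize and fix sign (positive tip-ward deflection near the base)
  for (k in seq_len(n_modes)) {
    nrm <- sqrt(sum(op$M * phi[, k]^2))
    phi[, k] <- phi[, k] / nrm
    if (phi[2, k] < 0) phi[, k] <- -phi[, k]
  }
  shapes <- rbind(0, phi)                  # prepend clamped base node
  list(omega = omega, s = op$s, shapes = shapes, op = op)
}

#' Natural frequency from the tapered-beam frequency law
#'
#' Evaluates `f_j = R_b / (4 pi S_tot^2) * sqrt(E / rho) * beta_j`, the
#' full-whisker form of the frequency law; the equivalent truncated form
#' uses `gamma_j = beta_j * l / S_tot` with prefactor
#' `R_b / (4 pi l S_tot)`.
#'
#' @param geom a [whisker_geometry()]
#' @param beta_j dimensionless full-whisker mode coefficient(s), >= 0
#' @return frequency in Hz (vectorized over `beta_j`)
#' @export
natural_frequency <- function(geom, beta_j) {
  stopifnot(all(beta_j >= 0))
  geom$R_b / (4 * pi * geom$S_tot^2) * sqrt(geom$E / geom$rho) * beta_j
}

#' Flexural group velocity of an Euler-Bernoulli rod
#'
#' Group velocity of a transverse wave packet in an infinite uniform rod of
#' radius `R`: `v_g = 2 * sqrt(omega) * (E R^2 / (4 rho))^(1/4)`. Flexural
#' waves are dispersive: `v_g` grows as the square root of frequency, which
#' is what temporally separates the modal wave packets of a collision
#' shockwave at the whisker base.
#'
#' @param E Young's modulus \[Pa\]
#' @param R rod radius \[m\]
#' @param rho density \[kg/m^3\]
#' @param omega angular frequency \[rad/s\]
#' @return group velocity \[m/s\] (vectorized over `omega`)
#' @examples
#' group_velocity(2e9, 60e-6, 1000, 2 * pi * 800)  # ~29 m/s
#' @export
group_velocity <- function(E, R, rho, omega) {
  stopifnot(E >= 0, R >= 0, rho > 0, all(omega >= 0))
  2 * sqrt(omega) * (E * R^2 / (4 * rho))^0.25
}

#' Static deflection of the tapered cantilever under a point load
#'
#' Solves `(E I(s) w'')'' = P delta(s - s0)` with clamped base and free tip
#' on the same discretization as [solve_eigenmodes()]. Used as the t = 0
#' state of [simulate_base_shear()]: immediately before slip-off the whisker
#' is statically bent against the pole by the contact force.
#'
#' @param geom a [whisker_geometry()]
#' @param load_position arc length of the point load from the base \[m\],
#'   in `(0, l]`
#' @param load transverse point force \[N\]
#' @param grid_size number of grid intervals
#' @return list with `s` (grid) and `w` (deflection \[m\] at `s`)
#' @export
static_deflection <- function(geom, load_position, load, grid_size = 400) {
  stopifnot(inherits(geom, "whisker_geometry"),
            load_position > 0, load_position <= geom$l)
  op <- beam_operators(geom, grid_size)
  f <- numeric(grid_size)
  idx <- max(1L, round(load_position / op$h))
  f[idx] <- load
  w <- c(0, solve(op$K, f))
  list(s = op$s, w = w)
}

#' Simulator configuration for the slip-off base-shear simulation
#'
#' @param pole_arc_position contact location, arc length measured from the
#'   tip of the truncated whisker \[m\] (the convention used when reporting
#'   pole positions "x mm from the tip")
#' @param alpha frequency-independent modal damping coefficient \[rad/s\];
#'   each modal amplitude decays as `exp(-alpha t)`
#' @param dt time step \[s\]
#' @param n_points number of time samples
#' @param n_modes modal truncation count
#' @param force_amplitude static point load applied at the pole before
#'   release \[N\]
#' @return a `simulator_config` list
#' @export
simulator_config <- function(pole_arc_position, alpha = 430, dt = 1e-5,
                             n_points = 10000, n_modes = 20,
                             force_amplitude = 5e-6) {
  stopifnot(dt > 0, n_points >= 2, n_modes >= 1, alpha >= 0,
            pole_arc_position >= 0)
  structure(list(pole_arc_position = pole_arc_position, alpha = alpha,
                 dt = dt, n_points = as.integer(n_points),
                 n_modes = as.integer(n_modes),
                 force_amplitude = force_amplitude),
            class = "simulator_config")
}

#' Simulate the shear force at the whisker base after a slip-off
#'
#' Free damped vibration of the whisker released from the static deflection
#' under a point load at the pole. The initial deflection is projected onto
#' the mass-normalized eigenmodes; each modal coordinate then evolves as a
#' damped oscillator with amplitude envelope `exp(-alpha t)` (damped angular
#' frequency `omega_d = sqrt(omega_n^2 - alpha^2)`; modes with
#' `omega_n <= alpha` follow the overdamped non-oscillatory branch). The
#' base shear is `E I(0) w'''(0)`, assembled mode-by-mode from one-sided
#' third-derivative stencils of the mode shapes at the clamped base.
#'
#' @param geom a [whisker_geometry()]
#' @param cfg a [simulator_config()]
#' @param modes optionally, a precomputed [solve_eigenmodes()] result with
#'   at least `cfg$n_modes` modes (must match `geom`)
#' @param grid_size grid used when `modes` is not supplied
#' @return a [voltage_trace()]-like object of class `force_trace`: sampled
#'   shear force \[N\] at rate `1/dt`, with attributes `modal` (data.frame:
#'   `j`, `f_j`, `omega_j`, `q0` initial modal coordinate, `c_shear` base
#'   shear per unit modal coordinate, `energy0` initial modal energy \[J\])
#'   and `alpha`.
#' @export
simulate_base_shear <- function(geom, cfg, modes = NULL, grid_size = 400) {
  stopifnot(inherits(cfg, "simulator_config"))
  if (cfg$pole_arc_position >= geom$l)
    stop("pole_arc_position (from tip) must be smaller than the truncated length")
  if (is.null(modes)) {
    modes <- solve_eigenmodes(geom, n_modes = cfg$n_modes,
                              grid_size = grid_size, check = FALSE)
  }
  if (nrow(modes$table) < cfg$n_modes)
    stop(sprintf("cfg$n_modes = %d exceeds the %d solved modes",
                 cfg$n_modes, nrow(modes$table)))
  op <- beam_operators(geom, length(modes$s) - 1L)
  load_s <- geom$l - cfg$pole_arc_position     # convert tip-based to base-based
  w0 <- static_deflection(geom, load_s, cfg$force_amplitude,
                          grid_size = length(modes$s) - 1L)$w
  jj <- seq_len(cfg$n_modes)
  phi <- modes$shapes[-1, jj, drop = FALSE]    # interior + tip nodes
  q0 <- as.numeric(crossprod(phi, op$M * w0[-1]))
  omega <- modes$table$omega_j[jj]
  c_shear <- op$EI0 * apply(modes$shapes[, jj, drop = FALSE], 2,
                            third_deriv_at_base, h = op$h)
  t <- (seq_len(cfg$n_points) - 1L) * cfg$dt
  a <- cfg$alpha
  force <- numeric(cfg$n_points)
  for (k in jj) {
    om <- omega[k]
    if (om > a) {
      od <- sqrt(om^2 - a^2)
      qk <- exp(-a * t) * (cos(od * t) + (a / od) * sin(od * t)) * q0[k]
    } else if (om < a) {
      nu <- sqrt(a^2 - om^2)
      qk <- exp(-a * t) * (cosh(nu * t) + (a / nu) * sinh(nu * t)) * q0[k]
    } else {
      qk <- exp(-a * t) * (1 + a * t) * q0[k]
    }
    force <- force + c_shear[k] * qk
  }
  out <- voltage_trace(force, sample_rate = 1 / cfg$dt, V_off = 0,
                       units = "N", gain_label = "simulated base shear")
  class(out) <- c("force_trace", class(out))
  attr(out, "modal") <- data.frame(j = jj, f_j = modes$table$f_j[jj],
                                   omega_j = omega, q0 = q0,
                                   c_shear = c_shear,
                                   energy0 = 0.5 * omega^2 * q0^2)
  attr(out, "alpha") <- a
  out
}

#' Modal energies of the simulated free vibration
#'
#' Energy of mode `j` at times `t` under the simulator's damping convention
#' (amplitude envelope `exp(-alpha t)`): `E_j(t) = (qdot^2 + omega^2 q^2)/2`
#' for mass-normalized coordinates. With `alpha = 0` each modal energy is
#' conserved; with `alpha > 0` the envelope of `E_j` decays as
#' `exp(-2 alpha t)`.
#'
#' @param sim result of [simulate_base_shear()]
#' @param t times \[s\]
#' @return matrix `length(t) x n_modes` of modal energies \[J\]
#' @export
simulated_modal_energy <- function(sim, t) {
  md <- attr(sim, "modal"); a <- attr(sim, "alpha")
  E <- matrix(0, length(t), nrow(md))
  for (k in seq_len(nrow(md))) {
    om <- md$omega_j[k]
    if (om > a) {
      od <- sqrt(om^2 - a^2)
      q <- exp(-a * t) * (cos(od * t) + (a / od) * sin(od * t)) * md$q0[k]
      qd <- -exp(-a * t) * (om^2 / od) * sin(od * t) * md$q0[k]
    } else if (om < a) {
      nu <- sqrt(a^2 - om^2)
      q <- exp(-a * t) * (cosh(nu * t) + (a / nu) * sinh(nu * t)) * md$q0[k]
      qd <- -exp(-a * t) * (om^2 / nu) * sinh(nu * t) * md$q0[k]
    } else {
      q <- exp(-a * t) * (1 + a * t) * md$q0[k]
      qd <- -exp(-a * t) * a^2 * t * md$q0[k]
    }
    E[, k] <- 0.5 * (qd^2 + om^2 * q^2)
  }
  E
}

# third derivative at the clamped base from the first three interior values,
# using w(0) = w'(0) = 0: solve the 3x3 Taylor system for (w'', w''', w'''')
third_deriv_at_base <- function(w, h) {
  i <- 1:3
  A <- cbind((i * h)^2 / 2, (i * h)^3 / 6, (i * h)^4 / 24)
  as.numeric(solve(A, w[2:4])[2])
}
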