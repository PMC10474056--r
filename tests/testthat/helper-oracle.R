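# Independent oracle: Hermite-cubic beam finite elements for the tapered
# clamped-free Euler-Bernoulli beam. A different discretization family from
# the package's finite-difference Rayleigh-Ritz scheme: two dofs (w, w') per
# node, classical 4x4 element stiffness/consistent-mass matrices with EI and
# rho*A evaluated at element midpoints.

oracle_fem_matrices <- function(geom, n_el) {
  h <- geom$l / n_el
  ndof <- 2 * (n_el + 1)
  K <- matrix(0, ndof, ndof)
  M <- matrix(0, ndof, ndof)
  ke0 <- matrix(c(12, 6, -12, 6,
                  6, 4, -6, 2,
                  -12, -6, 12, -6,
                  6, 2, -6, 4), 4, 4)
  me0 <- matrix(c(156, 22, 54, -13,
                  22, 4, 13, -3,
                  54, 13, 156, -22,
                  -13, -3, -22, 4), 4, 4)
  hs <- c(1, h, 1, h)
  for (e in seq_len(n_el)) {
    smid <- (e - 0.5) * h
    r <- geom$R_b - geom$slope_R * smid
    EI <- geom$E * pi * r^4 / 4
    rhoA <- geom$rho * pi * r^2
    ke <- (EI / h^3) * ke0 * outer(hs, hs)
    me <- (rhoA * h / 420) * me0 * outer(hs, hs)
    idx <- (2 * e - 1):(2 * e + 2)
    K[idx, idx] <- K[idx, idx] + ke
    M[idx, idx] <- M[idx, idx] + me
  }
  free <- 3:ndof                      # clamp w and w' at the base node
  list(K = K[free, free], M = M[free, free], h = h)
}

oracle_fem_modes <- function(geom, n_modes, n_el = 200) {
  op <- oracle_fem_matrices(geom, n_el)
  R <- chol((op$K + t(op$K)) / 2)
  Mi <- backsolve(R, t(chol((op$M + t(op$M)) / 2)), transpose = TRUE)
  ev <- eigen(tcrossprod(Mi), symmetric = TRUE, only.values = TRUE)
  omega <- 1 / sqrt(ev$values[seq_len(n_modes)])
  omega / (2 * pi)
}

oracle_fem_static <- function(geom, load_position, load, n_el = 200) {
  op <- oracle_fem_matrices(geom, n_el)
  f <- numeric(nrow(op$K))
  node <- round(load_position / op$h)        # nearest node, 1..n_el
  f[2 * node - 1] <- load                    # translational dof of that node
  R <- chol((op$K + t(op$K)) / 2)
  d <- backsolve(R, backsolve(R, f, transpose = TRUE))
  w <- c(0, d[seq(1, length(d), by = 2)])    # deflections at nodes 0..n_el
  list(s = seq(0, geom$l, length.out = n_el + 1), w = w)
}
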