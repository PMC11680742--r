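# Shared fixtures, built in code. Heavier objects are memoized so the
# suite generates each of them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# hand-built minimal transmit setup (bypasses the phantom generator so
# sta/bloch tests control every number)
toy_setup <- function(sens, db0 = 0, coords = NULL, weights = NULL) {
  sens <- as.matrix(sens)
  n <- nrow(sens)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  structure(list(
    grid_n = c(n, 1L, 1L), fov = 0.24, coords = coords,
    sens = sens, db0 = rep(db0, length.out = n), mask = rep(TRUE, n),
    weights = if (is.null(weights)) rep(1, n) else weights,
    m0 = 1, n_channels = ncol(sens), config = NULL
  ), class = "ptx_setup")
}

small_phantom <- function() memo("ph16", generate_phantom(phantom_config(grid_n = 16L, seed = 11L)))
small_safety <- function() memo("saf16", generate_safety_model(small_phantom()$setup, seq_timing(), seed = 11L))

default_phantom <- function() memo("ph32", generate_phantom(phantom_config(seed = 1L)))
default_safety <- function() memo("saf32", generate_safety_model(default_phantom()$setup, seq_timing(), seed = 1L))

wm_pars <- function() {
  list(r1f = 0.5, r1s = 3, k_fs = 2, k_sf = 2 * 0.87 / 0.13,
       m0f = 0.87, m0s = 0.13, t2s = 1e-5, lineshape = "gaussian")
}

# 3x3 rotation-composition Bloch oracle for one voxel (Matrix::expm route)
bloch_oracle <- function(pulse, setup, voxel = 1L) {
  gam <- gamma_1h()
  tm <- pulse$timing
  Fsub <- (setup$sens[voxel, , drop = FALSE] %*% pulse$rf) * 1e-6
  bz <- 2 * pi * setup$db0[voxel] / gam
  cross <- function(w) matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
                              3, 3, byrow = TRUE)
  M <- c(0, 0, 1)
  for (j in seq_len(tm$n_subpulses)) {
    w <- -gam * c(Re(Fsub[1, j]), Im(Fsub[1, j]), bz)
    R <- as.matrix(Matrix::expm(cross(w) * tm$dt))
    for (s in seq_len(tm$samples_per_subpulse)) M <- R %*% M
    if (j < tm$n_subpulses) {
      phi <- 2 * pi * setup$db0[voxel] * tm$blip_duration +
        sum(setup$coords[voxel, ] * pulse$blip_moments[j, ])
      Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
                   3, 3, byrow = TRUE)
      M <- Rz %*% M
    }
  }
  atan2(sqrt(M[1]^2 + M[2]^2), M[3])
}

# central finite differences of a scalar function
fd_grad <- function(fn, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    e <- x; e[i] <- x[i] + h; f1 <- fn(e)
    e[i] <- x[i] - h
    (f1 - fn(e)) / (2 * h)
  }, numeric(1))
}
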