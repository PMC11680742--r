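#' Configuration for the synthetic 8-channel head phantom
#'
#' Parameters of the synthetic transmit setup that emulates a human head in
#' an azimuthal 8-channel pTx coil at ultra-high field: an ellipsoidal mask
#' with concentric CSF/GM/WM compartments, per-channel complex sensitivities
#' whose circularly polarized (CP) combination shows central brightening,
#' and a smooth off-resonance field with one localized hotspot.
#'
#' The `brightening` knob scales both the per-channel magnitude decay and
#' the propagation-like phase accrual with distance from each channel;
#' at `brightening = 1` (with `gain_jitter = 0`) the channels combine to a
#' spatially flat CP field, while the default produces a center-to-edge CP
#' ratio comfortably above 1.3, the qualitative structure seen in vivo.
#'
#' @param grid_n Voxels per axis (scalar or length 3), >= 8.
#' @param fov Field of view, meters (isotropic).
#' @param n_channels Number of transmit channels.
#' @param brightening Central-brightening strength (1 = uniform CP field).
#' @param gain_jitter Relative SD of the seeded per-channel gain variation.
#' @param db0_range Half-range of the off-resonance field, Hz.
#' @param seed Integer seed; the phantom is bit-identical for a fixed
#'   config + seed.
#' @return A list of class `ptx_phantom_config`.
#' @export
phantom_config <- function(grid_n = 32L, fov = 0.24, n_channels = 8L,
                           brightening = 1.5, gain_jitter = 0.05,
                           db0_range = 150, seed = 1L) {
  grid_n <- as.integer(rep(grid_n, length.out = 3L))
  if (any(grid_n < 8L)) .stopf("grid_n must be >= 8 per axis")
  .check_scalar(fov, "fov", positive = TRUE)
  if (brightening < 1) .stopf("brightening must be >= 1")
  structure(list(grid_n = grid_n, fov = fov, n_channels = as.integer(n_channels),
                 brightening = brightening, gain_jitter = gain_jitter,
                 db0_range = db0_range, seed = as.integer(seed)),
            class = "ptx_phantom_config")
}

#' Circularly polarized channel weights
#'
#' The default fixed-phase combination \eqn{w_q = e^{-i 2\pi (q-1)/N_{ch}}}
#' used for the CP-mode pulse and for calibrating the SAR model.
#'
#' @param n_channels Number of channels.
#' @return Complex vector of unit-magnitude weights.
#' @export
cp_weights <- function(n_channels) {
  exp(-1i * 2 * pi * (seq_len(n_channels) - 1) / n_channels)
}

#' Complex combined transmit field for fixed channel weights
#'
#' @param setup A `ptx_setup` object.
#' @param w Complex weights, one per channel (volts if the result is to be
#'   read in microtesla).
#' @return Complex vector, one value per voxel, in microtesla.
#' @export
combined_field <- function(setup, w) {
  stopifnot(inherits(setup, "ptx_setup"), length(w) == setup$n_channels)
  as.vector(setup$sens %*% w)
}

#' Generate the synthetic transmit setup and tissue model
#'
#' Builds the full phantom: RAS-ordered voxel grid with voxel-center
#' coordinates relative to the mask centroid, ellipsoidal head mask with
#' concentric WM/GM/CSF shells, azimuthally placed channels with smooth
#' magnitude decay and geometric + propagation phase (so the CP combination
#' brightens centrally), and a low-order off-resonance field plus a
#' localized Gaussian hotspot. Deterministic for a fixed config.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `setup` (class `ptx_setup`) and `tissue`
#'   (class `ptx_tissue`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "ptx_phantom_config"))
  n <- config$grid_n; fov <- config$fov
  ax <- lapply(n, function(k) (seq_len(k) - (k + 1) / 2) / k * fov)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE)
  coords <- as.matrix(g)
  nv <- nrow(coords)

  # concentric ellipsoidal head: semi-axes scale with FOV
  semi <- c(0.070, 0.085, 0.075) * (fov / 0.24)
  rho <- sqrt((coords[, 1] / semi[1])^2 + (coords[, 2] / semi[2])^2 +
              (coords[, 3] / semi[3])^2)
  mask <- rho <= 1
  if (!any(mask)) .stopf("degenerate FOV: zero-volume mask")
  labels <- rep("background", nv)
  labels[mask] <- "CSF"
  labels[rho <= 0.90] <- "GM"
  labels[rho <= 0.65] <- "WM"

  nch <- config$n_channels
  eta <- config$brightening - 1
  out <- with_seed(config$seed, {
    theta <- 2 * pi * (seq_len(nch) - 1) / nch +
      stats::rnorm(nch, sd = 0.02)
    gains <- 1 + stats::rnorm(nch, sd = config$gain_jitter)
    rc <- 0.62 * fov                      # coil ring radius
    pos <- cbind(rc * cos(theta), rc * sin(theta),
                 stats::rnorm(nch, sd = 0.004))
    # per-channel distance maps
    sens <- matrix(0i, nv, nch)
    kappa <- 48 * eta                     # rad/m phase accrual with distance
    decay_l <- 0.22                       # m, magnitude decay length
    base <- 0.0030                        # muT/V per channel at the coil radius
    for (q in seq_len(nch)) {
      d <- sqrt((coords[, 1] - pos[q, 1])^2 + (coords[, 2] - pos[q, 2])^2 +
                (coords[, 3] - pos[q, 3])^2)
      mag <- base * gains[q] * exp(-eta * (d - rc) / decay_l)
      ph <- 2 * pi * (q - 1) / nch - kappa * (d - rc)
      sens[, q] <- mag * exp(1i * ph)
    }
    # off-resonance: low-order smooth field + one Gaussian hotspot
    s2 <- (fov / 2)^2
    low <- 40 * ((coords[, 1]^2 + coords[, 2]^2 - 2 * coords[, 3]^2) / s2) +
      15 * coords[, 1] / (fov / 2) + 10 * coords[, 2] / (fov / 2)
    ctr <- c(0.055, 0.005, 0.025) * (fov / 0.24) + stats::rnorm(3, sd = 0.003)
    d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
      (coords[, 3] - ctr[3])^2
    hot <- 110 * exp(-d2 / (2 * 0.03^2))
    db0 <- low + hot
    db0 <- db0 / max(abs(db0[mask])) * config$db0_range * 0.9
    list(sens = sens, db0 = db0)
  })

  weights <- as.numeric(mask)
  setup <- structure(list(
    grid_n = n, fov = fov, coords = coords,
    sens = out$sens, db0 = out$db0, mask = mask, weights = weights,
    m0 = 1, n_channels = nch, config = config
  ), class = "ptx_setup")

  tissue <- tissue_model(labels, grid_n = n)
  list(setup = setup, tissue = tissue)
}

#' @export
print.ptx_setup <- function(x, ...) {
  cat(sprintf("pTx transmit setup: %s grid, %.0f mm FOV, %d channels, %d masked voxels\n",
              paste(x$grid_n, collapse = "x"), x$fov * 1e3, x$n_channels,
              sum(x$mask)))
  invisible(x)
}

#' Two-pool tissue model on the phantom grid
#'
#' Per-voxel tissue labels with per-label binary spin-bath parameters:
#' free/semisolid longitudinal rates, exchange rates, pool fractions,
#' semisolid T2 and lineshape. The semisolid-to-free rate is always derived
#' from detailed balance, `k_sf = k_fs * M0f / M0s`, so the constructed
#' model satisfies `k_fs * M0f == k_sf * M0s` exactly.
#'
#' @param labels Character vector of per-voxel labels in
#'   `{"WM","GM","CSF","background"}`.
#' @param params Data frame of per-label parameters; defaults to
#'   [default_tissue_params()].
#' @param grid_n Grid dimensions (kept for reshaping maps).
#' @return An object of class `ptx_tissue`.
#' @export
tissue_model <- function(labels, params = default_tissue_params(), grid_n = NULL) {
  stopifnot(all(labels %in% c(params$label, "background")))
  if (any(params$r1f < 0 | params$r1s < 0 | params$k_fs < 0))
    .stopf("tissue rates must be >= 0")
  if (any(params$m0s < 0 | params$m0s >= 1)) .stopf("m0s must be in [0, 1)")
  params$m0f <- 1 - params$m0s
  params$k_sf <- ifelse(params$m0s > 0, params$k_fs * params$m0f / params$m0s, 0)
  # detailed balance forces k_fs = 0 where there is no semisolid pool
  params$k_fs[params$m0s == 0] <- 0
  structure(list(labels = labels, params = params, grid_n = grid_n),
            class = "ptx_tissue")
}

#' Default tissue parameters for the phantom compartments
#'
#' WM/GM values are plausible 7T binary spin-bath figures (free-pool rate
#' R1f in s^-1, semisolid rate R1s, forward exchange k_fs, semisolid
#' fraction M0s, semisolid T2 of 10 us); CSF is a free pool only. These are
#' configuration defaults for the simulator, not ground truth for any
#' subject.
#'
#' @return A data.frame with one row per label.
#' @export
default_tissue_params <- function() {
  data.frame(
    label = c("WM", "GM", "CSF"),
    r1f  = c(0.50, 0.35, 0.25),
    r1s  = c(3.0, 3.0, 3.0),
    k_fs = c(2.0, 1.0, 0.0),
    m0s  = c(0.13, 0.07, 0.0),
    t2s  = c(10e-6, 10e-6, 10e-6),
    t2f  = c(0.050, 0.060, 2.0),
    lineshape = c("gaussian", "gaussian", "gaussian"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ptx_tissue <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(x$params$label, "background")))
  cat("Two-pool tissue model; voxels per label:\n")
  print(tab)
  invisible(x)
}

# per-voxel parameter lookup for a set of voxel indices
.tissue_at <- function(tissue, idx) {
  lab <- tissue$labels[idx]
  p <- tissue$params
  m <- match(lab, p$label)
  list(label = lab,
       r1f = p$r1f[m], r1s = p$r1s[m], k_fs = p$k_fs[m], k_sf = p$k_sf[m],
       m0f = p$m0f[m], m0s = p$m0s[m], t2s = p$t2s[m],
       lineshape = p$lineshape[m])
}

#' Reshape a per-voxel vector to the phantom grid
#'
#' @param setup A `ptx_setup`.
#' @param values Per-voxel vector (full grid length); values outside the
#'   mask are kept as given.
#' @return A 3-D array with the phantom's grid dimensions.
#' @export
as_volume <- function(setup, values) {
  stopifnot(length(values) == prod(setup$grid_n))
  array(values, dim = setup$grid_n)
}
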