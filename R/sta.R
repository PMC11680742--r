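#' Excitation k-space trajectory of a kT-points pulse
#'
#' The excitation k-space location of each RF sample, using the reversed
#' cumulative convention: \eqn{k(t) = -\gamma \int_t^\tau G(t')\,dt'}, so
#' the final subpulse sits at k = 0 and earlier subpulses accumulate the
#' negatives of the subsequent blip moments. Only the blip moments matter;
#' k is piecewise constant across each subpulse.
#'
#' @param pulse A [kt_pulse()].
#' @return A `n_samples x 3` matrix, rad/m.
#' @export
excitation_kspace <- function(pulse) {
  tm <- pulse$timing
  kj <- .subpulse_kspace(pulse$blip_moments, tm$n_subpulses)
  kj[tm$subpulse_of, , drop = FALSE]
}

# per-subpulse k locations (n_subpulses x 3)
.subpulse_kspace <- function(blip_moments, n_subpulses) {
  kj <- matrix(0, n_subpulses, 3)
  if (n_subpulses > 1L && nrow(blip_moments)) {
    # subpulse j sits at -(sum of blips j..n-1)
    rev_cum <- apply(blip_moments, 2, function(v) rev(cumsum(rev(v))))
    rev_cum <- matrix(rev_cum, ncol = 3)
    kj[seq_len(n_subpulses - 1L), ] <- -rev_cum
  }
  kj
}

#' Small-tip-angle system matrix
#'
#' The spatial-domain system matrix with elements
#' \deqn{A_{mn} = i \gamma m_0 \Delta t\, e^{i 2\pi \Delta B_0(r_m)(t_n - \tau)}
#'       e^{i r_m \cdot k(t_n)}}
#' over masked voxels (rows) and RF-on samples (columns). Off-resonance is
#' map-native Hz, hence the \eqn{2\pi} in the phase. Every entry has
#' modulus \eqn{\gamma m_0 \Delta t}.
#'
#' @param setup A `ptx_setup`.
#' @param timing A [seq_timing()].
#' @param k `n_samples x 3` trajectory from [excitation_kspace()].
#' @param voxels Integer indices of voxels to include (default: masked).
#' @return Complex matrix, `length(voxels) x n_samples`. Units 1/T per volt
#'   of (sensitivity-weighted) drive once multiplied by a field in tesla.
#' @export
system_matrix <- function(setup, timing, k, voxels = which(setup$mask)) {
  stopifnot(inherits(setup, "ptx_setup"), inherits(timing, "ptx_timing"))
  k <- as.matrix(k)
  if (nrow(k) != timing$n_samples || ncol(k) != 3L)
    .stopf("k must be n_samples x 3 (%d x 3)", timing$n_samples)
  r <- setup$coords[voxels, , drop = FALSE]
  phase_off <- outer(2 * pi * setup$db0[voxels], timing$t - timing$tau) # Ns x Nt
  phase_k <- tcrossprod(r, k)                                          # Ns x Nt
  (1i * gamma_1h() * setup$m0 * timing$dt) * exp(1i * (phase_off + phase_k))
}

#' Small-tip-angle flip angle map
#'
#' \eqn{\alpha_m = |\sum_q s_q(r_m) (A b_q)_m| / m_0}: the magnitude of the
#' transverse magnetization predicted by the small-tip approximation,
#' ignoring excitation phase. Linear in the overall RF scale.
#'
#' @param pulse A [kt_pulse()].
#' @param setup A `ptx_setup`.
#' @param A Optional precomputed [system_matrix()] for the same voxels.
#' @param voxels Voxel indices (default: masked voxels).
#' @return Numeric vector of flip angles, radians, one per voxel in `voxels`.
#' @export
flip_angle_map <- function(pulse, setup, A = NULL, voxels = which(setup$mask)) {
  tm <- pulse$timing
  if (is.null(A)) A <- system_matrix(setup, tm, excitation_kspace(pulse), voxels)
  if (ncol(A) != tm$n_samples || nrow(A) != length(voxels))
    .stopf("system matrix dimensions do not match setup/timing")
  b <- .rf_per_sample(pulse)                      # Nch x Nt, volts
  m <- numeric(length(voxels)) + 0i
  for (q in seq_len(pulse$n_channels)) {
    m <- m + (setup$sens[voxels, q] * .UT) * as.vector(A %*% b[q, ])
  }
  Mod(m) / setup$m0
}

#' Sequence B1rms map
#'
#' Root-mean-squared combined transmit field over one TR:
#' \deqn{\beta_m = \sqrt{\frac{1}{TR}\sum_n \Delta t\,
#'   \left|\sum_q s_q(r_m) b_q(t_n)\right|^2}}
#' in microtesla. Independent of the gradient blips; scales linearly with
#' the RF amplitude.
#'
#' @inheritParams flip_angle_map
#' @return Numeric vector, microtesla, one value per voxel in `voxels`.
#' @export
b1rms_map <- function(pulse, setup, voxels = which(setup$mask)) {
  tm <- pulse$timing
  cmat <- setup$sens[voxels, , drop = FALSE] %*% pulse$rf   # Ns x n_sub, muT
  sqrt(tm$subpulse_duration / tm$tr * rowSums(Mod(cmat)^2))
}

#' Pulse shape factors of a unit-normalized envelope
#'
#' For an RF envelope normalized to unit duration and unit peak amplitude,
#' `p1` is its integral and `p2` the integral of its squared magnitude,
#' both over the unit interval. They link on-resonance flip angle and
#' B1rms for a given waveform support.
#'
#' @param waveform Samples of the unit-normalized envelope (uniformly
#'   spaced over the support; max modulus must be 1).
#' @return A list with `p1` and `p2` (class `ptx_shape`).
#' @export
pulse_shape_factors <- function(waveform) {
  if (length(waveform) == 0L) .stopf("empty waveform")
  pk <- max(Mod(waveform))
  if (abs(pk - 1) > 1e-9) .stopf("waveform must be normalized to unit amplitude")
  structure(list(p1 = mean(Re(waveform)), p2 = mean(Mod(waveform)^2)),
            class = "ptx_shape")
}

#' Shape factors of the rectangular kT-points train
#'
#' The binary on/off envelope of a kT-points train: `n` subpulses of equal
#' amplitude with zero-RF blip gaps, giving `p1 = p2 = on-time / tau`.
#'
#' @param timing A [seq_timing()].
#' @return A `ptx_shape` list.
#' @export
kt_shape_factors <- function(timing) {
  n_on <- timing$n_samples
  n_tot <- round(timing$tau / timing$dt)
  w <- rep(0, n_tot)
  # place ones where RF is on
  on <- rep(FALSE, n_tot)
  nsps <- timing$samples_per_subpulse
  nbl <- round(timing$blip_duration / timing$dt)
  pos <- 0L
  for (j in seq_len(timing$n_subpulses)) {
    on[pos + seq_len(nsps)] <- TRUE
    pos <- pos + nsps + nbl
  }
  w[on] <- 1
  stopifnot(sum(w) == n_on)
  pulse_shape_factors(w)
}

#' Minimum B1rms needed to reach a target on-resonance flip angle
#'
#' The lower bound
#' \deqn{\beta_{min} = \frac{\sqrt{p_2}}{\gamma p_1 \sqrt{TR\,\tau}}\,\alpha_{des}}
#' relating the flip angle of an on-resonance pulse of a given waveform to
#' the sequence B1rms it produces. `tau`, `p1` and `p2` must refer to the
#' same waveform support; the bound is invariant to zero-padding the
#' waveform (which rescales all three consistently).
#'
#' @param alpha_des Target flip angle, radians (> 0, or 0 for a zero bound).
#' @param shape A `ptx_shape` from [pulse_shape_factors()] /
#'   [kt_shape_factors()].
#' @param timing A [seq_timing()] supplying TR and tau.
#' @return The bound, microtesla.
#' @export
beta_min <- function(alpha_des, shape, timing) {
  if (alpha_des < 0) .stopf("alpha_des must be >= 0")
  if (shape$p1 <= 0) .stopf("waveform has no on-resonance flip (p1 = 0)")
  alpha_des * sqrt(shape$p2) /
    (gamma_1h() * shape$p1 * sqrt(timing$tr * timing$tau)) / .UT
}
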