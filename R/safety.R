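#' Default hardware and SAR limits
#'
#' Operating limits for an 8-channel head transmit system: 10 g local SAR
#' 20 W/kg, per-channel peak voltage 207 V, per-channel average power 24 W,
#' gradient amplitude 30 mT/m, slew rate 80 T/m/s. The global-SAR limit is
#' disabled (`NA`) unless set.
#'
#' @param sar_10g_max W/kg. @param v_max Volts. @param p_max Watts.
#' @param g_amp_max T/m. @param g_slew_max T/m/s.
#' @param sar_global_max W/kg, or `NA` to disable the global-SAR constraint.
#' @return A named list of limits.
#' @export
default_limits <- function(sar_10g_max = 20, v_max = 207, p_max = 24,
                           g_amp_max = 30e-3, g_slew_max = 80,
                           sar_global_max = NA_real_) {
  list(sar_10g_max = sar_10g_max, v_max = v_max, p_max = p_max,
       g_amp_max = g_amp_max, g_slew_max = g_slew_max,
       sar_global_max = sar_global_max)
}

.check_hermitian <- function(Q, name = "Q") {
  if (max(Mod(Q - Conj(t(Q)))) > 1e-10 * max(1, max(Mod(Q))))
    .stopf("%s must be Hermitian", name)
  invisible(Q)
}

#' Generate a synthetic compressed local-SAR model
#'
#' Builds a global power-deposition matrix and a set of virtual observation
#' point (VOP) matrices, all Hermitian positive semidefinite by
#' construction (`A %*% Conj(t(A))` from seeded random complex matrices).
#' The matrices are calibrated so that a reference CP-mode rectangular
#' pulse whose amplitude reaches the target flip angle in the least-squares
#' sense deposits `sar_fraction` of the 10 g limit at the worst VOP; the
#' global matrix is scaled so the same pulse deposits 40% of that local
#' value (local SAR dominating, as is typical). This stands in for a
#' vendor-provided SAR model; it is synthetic.
#'
#' @param setup A `ptx_setup` (used only for the calibration pulse).
#' @param timing A [seq_timing()] for the calibration pulse's TR.
#' @param n_vop Number of VOP matrices (>= 1).
#' @param seed Integer seed.
#' @param sar_fraction Fraction of `sar_10g_max` the reference CP pulse
#'   deposits (default 0.25).
#' @param alpha_ref Reference flip angle for calibration, radians.
#' @param limits A [default_limits()] list.
#' @return An object of class `ptx_safety` with `q_global`, `vops`,
#'   `limits`, `n_channels`.
#' @export
generate_safety_model <- function(setup, timing = seq_timing(),
                                  n_vop = 8L, seed = 1L, sar_fraction = 0.25,
                                  alpha_ref = deg2rad(15),
                                  limits = default_limits()) {
  stopifnot(inherits(setup, "ptx_setup"))
  n_vop <- as.integer(n_vop)
  if (n_vop < 1L) .stopf("n_vop must be >= 1")
  nch <- setup$n_channels
  raw <- with_seed(seed + 1000L, {
    mk <- function() {
      A <- matrix(complex(real = stats::rnorm(nch * nch),
                          imaginary = stats::rnorm(nch * nch)), nch, nch)
      Q <- A %*% Conj(t(A))
      Q / Re(sum(diag(Q))) * nch          # trace-normalized
    }
    list(qg = mk(), vops = replicate(n_vop, mk(), simplify = FALSE))
  })
  # calibration: CP single-rectangle pulse reaching alpha_ref (LS-optimal)
  ref <- cp_reference_pulse(setup, alpha_ref, tr = timing$tr)
  model <- structure(list(q_global = raw$qg, vops = raw$vops,
                          limits = limits, n_channels = nch),
                     class = "ptx_safety")
  loc <- local_sar(ref, model)$max
  if (loc <= 0) .stopf("degenerate calibration pulse (zero local SAR)")
  f_loc <- sar_fraction * limits$sar_10g_max / loc
  model$vops <- lapply(model$vops, function(Q) Q * f_loc)
  glob <- sar_quadratic(ref, raw$qg, timing$tr)
  model$q_global <- raw$qg * (0.4 * sar_fraction * limits$sar_10g_max / glob)
  model
}

#' @export
print.ptx_safety <- function(x, ...) {
  cat(sprintf("SAR/hardware model: %d channels, %d VOPs; SAR10g<=%g W/kg, Vmax=%g V, Pmax=%g W\n",
              x$n_channels, length(x$vops), x$limits$sar_10g_max,
              x$limits$v_max, x$limits$p_max))
  invisible(x)
}

# CP-mode single-rectangle pulse at the LS-optimal amplitude for alpha_des
cp_reference_pulse <- function(setup, alpha_des, tr) {
  tm1 <- seq_timing(tr = tr, n_subpulses = 1L)
  w <- cp_weights(setup$n_channels)
  a_unit <- flip_angle_map(kt_pulse(matrix(w, ncol = 1), timing = tm1), setup)
  wts <- setup$weights[setup$mask]
  c_star <- sum(wts * a_unit * alpha_des) / sum(wts * a_unit^2)
  kt_pulse(matrix(w * c_star, ncol = 1), timing = tm1)
}

#' Time-averaged SAR quadratic form
#'
#' \deqn{\mathrm{SAR}(b) = \frac{1}{TR}\sum_n \Delta t\, b(t_n)^H Q\, b(t_n)}
#' for a Hermitian PSD deposition matrix `Q` in W/kg per V^2.
#'
#' @param pulse A [kt_pulse()].
#' @param Q Hermitian `n_channels x n_channels` matrix.
#' @param tr Repetition time, s (default: the pulse's).
#' @return SAR in W/kg (real, >= 0; scales as |c|^2 with RF scale c).
#' @export
sar_quadratic <- function(pulse, Q, tr = pulse$timing$tr) {
  .check_hermitian(Q)
  b <- pulse$rf                                   # Nch x n_sub
  val <- sum(Re(Conj(b) * (Q %*% b))) * pulse$timing$subpulse_duration / tr
  max(Re(val), 0)
}

#' Worst-case local SAR over the VOP set
#'
#' @param pulse A [kt_pulse()].
#' @param safety A `ptx_safety` model.
#' @return A list with `max` (W/kg), `argmax` (VOP index), `per_vop`.
#' @export
local_sar <- function(pulse, safety) {
  if (length(safety$vops) < 1L) .stopf("empty VOP list")
  vals <- vapply(safety$vops, function(Q) sar_quadratic(pulse, Q), numeric(1))
  list(max = max(vals), argmax = which.max(vals), per_vop = vals)
}

#' Per-channel time-averaged RF power
#'
#' Forward power into a 50 ohm load with the 1/2 peak-to-average factor for
#' a constant envelope: \eqn{P_q = \frac{1}{TR}\sum_n \Delta t |b_q(t_n)|^2 / 100}.
#' The hardware power limit is interpreted against this definition.
#'
#' @param pulse A [kt_pulse()].
#' @param tr Repetition time, s.
#' @return Numeric vector, watts per channel.
#' @export
channel_power <- function(pulse, tr = pulse$timing$tr) {
  rowSums(Mod(pulse$rf)^2) * pulse$timing$subpulse_duration / tr / 100
}

#' Largest blip moment realizable within a blip duration
#'
#' Area of the largest symmetric triangle (or amplitude-clipped trapezoid)
#' gradient lobe fitting in `blip_duration` under amplitude and slew
#' limits, converted to a k-space increment \eqn{\Delta k = \gamma \cdot area}.
#'
#' @param blip_duration Seconds.
#' @param g_amp_max T/m. @param g_slew_max T/m/s.
#' @return Maximum |blip moment| per axis, rad/m.
#' @export
max_blip_moment <- function(blip_duration, g_amp_max = 30e-3, g_slew_max = 80) {
  if (blip_duration <= 0) return(0)
  peak <- g_slew_max * blip_duration / 2
  area <- if (peak <= g_amp_max) {
    blip_duration^2 * g_slew_max / 4
  } else {
    g_amp_max * (blip_duration - g_amp_max / g_slew_max)
  }
  gamma_1h() * area
}

#' Evaluate all operational constraints of a pulse
#'
#' Global SAR (if enabled), worst-VOP local SAR, per-channel average power,
#' per-channel peak voltage, and per-blip feasibility against the largest
#' realizable blip moment. Margins are `(limit - value)/limit`;
#' `all_satisfied` is the conjunction of all margins being nonnegative
#' (within `tol`).
#'
#' @param pulse A [kt_pulse()].
#' @param safety A `ptx_safety` model.
#' @param tol Numerical slack on the margins (default 1e-9).
#' @return A list of class `ptx_constraints`; `as_tibble()`-able via
#'   [constraint_table()].
#' @export
check_constraints <- function(pulse, safety, tol = 1e-9) {
  lim <- safety$limits
  ls <- local_sar(pulse, safety)
  pw <- channel_power(pulse)
  pv <- apply(Mod(pulse$rf), 1, max)
  dkmax <- max_blip_moment(pulse$timing$blip_duration, lim$g_amp_max, lim$g_slew_max)
  blip_ok <- if (nrow(pulse$blip_moments)) {
    apply(abs(pulse$blip_moments) <= dkmax + tol, 1, all)
  } else logical(0)
  sar_g <- sar_quadratic(pulse, safety$q_global)
  margins <- c(
    sar_local = (lim$sar_10g_max - ls$max) / lim$sar_10g_max,
    power = (lim$p_max - max(pw)) / lim$p_max,
    voltage = (lim$v_max - max(pv)) / lim$v_max,
    blip = if (length(blip_ok)) (dkmax - max(abs(pulse$blip_moments))) / dkmax else 1
  )
  if (is.finite(lim$sar_global_max))
    margins <- c(margins, sar_global = (lim$sar_global_max - sar_g) / lim$sar_global_max)
  structure(list(
    sar_global = sar_g, sar_local_max = ls$max, sar_local_argmax = ls$argmax,
    sar_per_vop = ls$per_vop, power_per_channel = pw,
    peak_voltage_per_channel = pv, blip_feasible = blip_ok,
    max_blip = dkmax, margins = margins,
    all_satisfied = all(margins >= -tol)
  ), class = "ptx_constraints")
}

#' Constraint report as a tibble
#'
#' @param report A `ptx_constraints` from [check_constraints()].
#' @return A tibble with one row per constraint: value, limit, margin.
#' @export
constraint_table <- function(report) {
  stopifnot(inherits(report, "ptx_constraints"))
  nm <- names(report$margins)
  tibble::tibble(
    constraint = nm,
    value = vapply(nm, function(n) switch(n,
      sar_local = report$sar_local_max,
      sar_global = report$sar_global,
      power = max(report$power_per_channel),
      voltage = max(report$peak_voltage_per_channel),
      blip = report$max_blip * (1 - report$margins[["blip"]])
    ), numeric(1)),
    margin = as.numeric(report$margins),
    satisfied = report$margins >= -1e-9
  )
}

#' @export
print.ptx_constraints <- function(x, ...) {
  cat(sprintf("Constraints %s: SAR10g %.3g W/kg (VOP %d), maxP %.3g W, maxV %.4g V\n",
              if (x$all_satisfied) "satisfied" else "VIOLATED",
              x$sar_local_max, x$sar_local_argmax,
              max(x$power_per_channel), max(x$peak_voltage_per_channel)))
  invisible(x)
}
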