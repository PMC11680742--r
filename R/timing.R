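#' Sequence and pulse timing for a kT-points train
#'
#' Timing container for a train of rectangular RF subpulses separated by
#' zero-RF gradient blips inside a repeating gradient-echo sequence.
#' The total pulse duration is
#' `tau = n_subpulses * subpulse_duration + (n_subpulses - 1) * blip_duration`.
#' RF time samples exist only where RF can be nonzero: the blip gaps carry
#' no samples of the small-tip system matrix.
#'
#' @param tr Repetition time, seconds. Must exceed `tau`.
#' @param n_subpulses Number of rectangular subpulses (default 5).
#' @param subpulse_duration Subpulse duration, seconds (default 200e-6).
#' @param blip_duration Gradient-blip duration, seconds (default 100e-6).
#' @param dt RF sample step, seconds (default 10e-6); must divide
#'   `subpulse_duration`.
#' @return An object of class `ptx_timing` with derived fields `tau`
#'   (pulse duration, s), `n_samples` (RF-on samples), `t` (sample-midpoint
#'   times, s), `subpulse_of` (subpulse index per sample).
#' @export
seq_timing <- function(tr = 8e-3, n_subpulses = 5L,
                       subpulse_duration = 200e-6, blip_duration = 100e-6,
                       dt = 10e-6) {
  .check_scalar(tr, "tr", positive = TRUE)
  .check_scalar(subpulse_duration, "subpulse_duration", positive = TRUE)
  .check_scalar(dt, "dt", positive = TRUE)
  n_subpulses <- as.integer(n_subpulses)
  if (n_subpulses < 1L) .stopf("n_subpulses must be >= 1")
  if (n_subpulses > 1L) .check_scalar(blip_duration, "blip_duration", positive = TRUE)
  nsps <- subpulse_duration / dt
  if (abs(nsps - round(nsps)) > 1e-9) .stopf("dt must divide subpulse_duration")
  nsps <- as.integer(round(nsps))
  tau <- n_subpulses * subpulse_duration + (n_subpulses - 1L) * blip_duration
  if (tr <= tau) .stopf("TR (%g s) must exceed total pulse duration tau (%g s)", tr, tau)
  # midpoint times of each RF sample within the train
  starts <- (seq_len(n_subpulses) - 1L) * (subpulse_duration + blip_duration)
  t <- as.vector(vapply(starts, function(s0) s0 + (seq_len(nsps) - 0.5) * dt,
                        numeric(nsps)))
  structure(list(
    tr = tr, n_subpulses = n_subpulses,
    subpulse_duration = subpulse_duration, blip_duration = blip_duration,
    dt = dt, tau = tau, samples_per_subpulse = nsps,
    n_samples = n_subpulses * nsps, t = t,
    subpulse_of = rep(seq_len(n_subpulses), each = nsps)
  ), class = "ptx_timing")
}

#' @export
print.ptx_timing <- function(x, ...) {
  cat(sprintf("kT-points timing: %d x %.0f us subpulses, %d x %.0f us blips, tau = %.2f ms, TR = %.2f ms\n",
              x$n_subpulses, x$subpulse_duration * 1e6,
              max(x$n_subpulses - 1L, 0L), x$blip_duration * 1e6,
              x$tau * 1e3, x$tr * 1e3))
  invisible(x)
}

#' Construct a kT-points pulse
#'
#' The design variable of the hybrid optimization: per-channel complex
#' subpulse amplitudes (volts) plus the gradient-blip moments (excitation
#' k-space increments, rad/m) between consecutive subpulses.
#'
#' @param rf Complex matrix, `n_channels x n_subpulses`, volts.
#' @param blip_moments Real matrix, `(n_subpulses - 1) x 3`, rad/m. May be
#'   `NULL` for a single subpulse.
#' @param timing A [seq_timing()] object.
#' @return An object of class `ptx_pulse`.
#' @export
kt_pulse <- function(rf, blip_moments = NULL, timing = seq_timing()) {
  rf <- as.matrix(rf)
  storage.mode(rf) <- "complex"
  if (ncol(rf) != timing$n_subpulses)
    .stopf("rf must have %d columns (one per subpulse)", timing$n_subpulses)
  nb <- timing$n_subpulses - 1L
  if (nb == 0L) {
    blip_moments <- matrix(0, 0, 3)
  } else {
    if (is.null(blip_moments)) blip_moments <- matrix(0, nb, 3)
    blip_moments <- matrix(as.numeric(blip_moments), nb, 3)
  }
  if (any(!is.finite(Mod(rf)))) .stopf("rf amplitudes must be finite")
  structure(list(rf = rf, blip_moments = blip_moments, timing = timing,
                 n_channels = nrow(rf)),
            class = "ptx_pulse")
}

#' @export
print.ptx_pulse <- function(x, ...) {
  cat(sprintf("kT-points pulse: %d channels x %d subpulses, max |RF| = %.1f V, max |blip| = %.1f rad/m\n",
              x$n_channels, x$timing$n_subpulses, max(Mod(x$rf)),
              if (nrow(x$blip_moments)) max(abs(x$blip_moments)) else 0))
  invisible(x)
}

# expand per-subpulse RF to per-sample (n_channels x n_samples)
.rf_per_sample <- function(pulse) {
  pulse$rf[, pulse$timing$subpulse_of, drop = FALSE]
}
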