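# Serialization: NIfTI volumes for maps and fields, JSON for pulses and
# the SAR model, YAML for configs. Complex quantities go to disk as
# magnitude+phase NIfTI pairs or [re, im] JSON pairs.

.write_vol <- function(setup, values, path) {
  arr <- as_volume(setup, values)
  vox <- setup$fov / setup$grid_n
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, vox, rep(0, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a per-voxel map as NIfTI
#'
#' @param setup The `ptx_setup` carrying grid geometry.
#' @param values Full-grid per-voxel vector (e.g. a design result's
#'   `alpha_map`).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_map <- function(setup, values, path) .write_vol(setup, values, path)

#' Write a transmit setup to a directory
#'
#' One magnitude + one phase NIfTI per channel, plus off-resonance, mask
#' and weight volumes and a YAML geometry sidecar.
#'
#' @param setup A `ptx_setup`. @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_setup <- function(setup, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (q in seq_len(setup$n_channels)) {
    .write_vol(setup, Mod(setup$sens[, q]), file.path(dir, sprintf("sens_mag_ch%02d.nii.gz", q)))
    .write_vol(setup, Arg(setup$sens[, q]), file.path(dir, sprintf("sens_phase_ch%02d.nii.gz", q)))
  }
  .write_vol(setup, setup$db0, file.path(dir, "db0_hz.nii.gz"))
  .write_vol(setup, as.numeric(setup$mask), file.path(dir, "mask.nii.gz"))
  .write_vol(setup, setup$weights, file.path(dir, "weights.nii.gz"))
  yaml::write_yaml(list(grid_n = setup$grid_n, fov_m = setup$fov,
                        n_channels = setup$n_channels, m0 = setup$m0),
                   file.path(dir, "setup.yaml"))
  invisible(dir)
}

#' Read a transmit setup written by [write_setup()]
#'
#' @param dir Directory containing the setup files.
#' @return A `ptx_setup`.
#' @export
read_setup <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "setup.yaml"))
  n <- as.integer(meta$grid_n); fov <- meta$fov_m
  rd <- function(f) as.vector(RNifti::readNifti(file.path(dir, f)))
  nch <- meta$n_channels
  sens <- matrix(0i, prod(n), nch)
  for (q in seq_len(nch)) {
    mag <- rd(sprintf("sens_mag_ch%02d.nii.gz", q))
    ph <- rd(sprintf("sens_phase_ch%02d.nii.gz", q))
    sens[, q] <- mag * exp(1i * ph)
  }
  ax <- lapply(n, function(k) (seq_len(k) - (k + 1) / 2) / k * fov)
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  structure(list(grid_n = n, fov = fov, coords = coords, sens = sens,
                 db0 = rd("db0_hz.nii.gz"), mask = rd("mask.nii.gz") > 0.5,
                 weights = rd("weights.nii.gz"), m0 = meta$m0,
                 n_channels = nch, config = NULL),
            class = "ptx_setup")
}

#' Write a kT-points pulse as JSON
#'
#' Per-channel complex subpulse amplitudes as \[re, im\] volt pairs, blip
#' moments in rad/m, and the timing block.
#'
#' @param pulse A [kt_pulse()]. @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_pulse <- function(pulse, path) {
  tm <- pulse$timing
  obj <- list(
    rf_volts = .cplx_to_json(pulse$rf),
    blip_moments_rad_per_m = apply(pulse$blip_moments, 1, as.numeric,
                                   simplify = FALSE),
    timing = list(tr_s = tm$tr, n_subpulses = tm$n_subpulses,
                  subpulse_duration_s = tm$subpulse_duration,
                  blip_duration_s = tm$blip_duration, dt_s = tm$dt)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a pulse written by [write_pulse()]
#' @param path JSON path.
#' @return A `ptx_pulse`.
#' @export
read_pulse <- function(path) {
  obj <- jsonlite::read_json(path)
  tmj <- obj$timing
  tm <- seq_timing(tr = tmj$tr_s, n_subpulses = tmj$n_subpulses,
                   subpulse_duration = tmj$subpulse_duration_s,
                   blip_duration = tmj$blip_duration_s, dt = tmj$dt_s)
  rf <- .json_to_cplx(obj$rf_volts)
  g <- if (length(obj$blip_moments_rad_per_m))
    do.call(rbind, lapply(obj$blip_moments_rad_per_m, unlist)) else NULL
  kt_pulse(rf, g, tm)
}

#' Write / read the SAR safety model as JSON
#'
#' Complex matrices are stored as nested \[re, im\] pairs.
#'
#' @param model A `ptx_safety`. @param path JSON path.
#' @return `path` (write) or a `ptx_safety` (read).
#' @export
write_safety <- function(model, path) {
  obj <- list(n_channels = model$n_channels,
              q_global = .cplx_to_json(model$q_global),
              vops = lapply(model$vops, .cplx_to_json),
              limits = model$limits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_safety
#' @export
read_safety <- function(path) {
  obj <- jsonlite::read_json(path)
  lim <- lapply(obj$limits, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  structure(list(q_global = .json_to_cplx(obj$q_global),
                 vops = lapply(obj$vops, .json_to_cplx),
                 limits = lim, n_channels = obj$n_channels),
            class = "ptx_safety")
}

#' Write a design result (pulse + maps + metrics)
#'
#' @param result A `ptx_design`. @param setup The matching `ptx_setup`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_design <- function(result, setup, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pulse(result$pulse, file.path(dir, "pulse.json"))
  .write_vol(setup, result$alpha_map, file.path(dir, "alpha_rad.nii.gz"))
  .write_vol(setup, result$beta_map, file.path(dir, "beta_ut.nii.gz"))
  meta <- list(mode = result$mode, lambda = result$lambda,
               alpha_des_rad = result$alpha_des, beta_des_ut = result$beta_des,
               nrmse_alpha = result$nrmse_alpha, nrmse_beta = result$nrmse_beta,
               cost = result$cost, converged = result$converged,
               start_index = result$start_index,
               start_costs = result$start_costs,
               margins = as.list(result$constraints$margins))
  jsonlite::write_json(meta, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
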