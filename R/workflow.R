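#' Experiment configuration
#'
#' Validated nested configuration for the end-to-end pipeline: phantom,
#' SAR model, sequence timing, design targets, simulation and report
#' blocks, plus one global seed that controls every stochastic stage.
#' Keys carry explicit units in their names. Unknown keys are rejected.
#'
#' @param phantom,safety,timing,design,simulation,report Named lists
#'   overriding the defaults of the corresponding block.
#' @param seed Global integer seed.
#' @return A list of class `ptx_config`.
#' @export
experiment_config <- function(phantom = list(), safety = list(),
                              timing = list(), design = list(),
                              simulation = list(), report = list(),
                              seed = 1L) {
  defaults <- list(
    phantom = list(grid_n = 32L, fov_mm = 240, n_channels = 8L,
                   brightening = 1.5, gain_jitter = 0.05, db0_range_hz = 150),
    safety = list(n_vop = 8L, sar_fraction = 0.25, sar_10g_max = 20,
                  v_max = 207, p_max = 24, g_amp_max_mt_per_m = 30,
                  g_slew_max = 80, sar_global_max = NA),
    timing = list(tr_ms = 8, n_subpulses = 5L, subpulse_us = 200,
                  blip_us = 100, dt_us = 10),
    design = list(alpha_des_deg = c(3, 15), lambda = 0.5,
                  beta_des_rule = "1.2*beta_min", beta_des_ut = NULL,
                  n_starts = 10L, n_clusters = 500L),
    simulation = list(noise_sd = 0),
    report = list(pulse_types = c("fa", "hy"))
  )
  blocks <- list(phantom = phantom, safety = safety, timing = timing,
                 design = design, simulation = simulation, report = report)
  cfg <- list()
  for (nm in names(defaults)) {
    user <- blocks[[nm]]
    bad <- setdiff(names(user), names(defaults[[nm]]))
    if (length(bad))
      .stopf("unknown key(s) in '%s' block: %s", nm, paste(bad, collapse = ", "))
    cfg[[nm]] <- utils::modifyList(defaults[[nm]], user)
  }
  cfg$seed <- as.integer(seed)
  if (!all(cfg$report$pulse_types %in% c("cp", "shim", "fa", "hy")))
    .stopf("pulse_types must be among cp, shim, fa, hy")
  structure(cfg, class = "ptx_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose top-level blocks match
#'   [experiment_config()].
#' @return A validated `ptx_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else y$seed
  known <- c("phantom", "safety", "timing", "design", "simulation",
             "report", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) .stopf("unknown top-level key(s): %s", paste(bad, collapse = ", "))
  y$seed <- NULL
  do.call(experiment_config, c(y, list(seed = seed)))
}

.cfg_timing <- function(cfg) {
  tc <- cfg$timing
  seq_timing(tr = tc$tr_ms * 1e-3, n_subpulses = tc$n_subpulses,
             subpulse_duration = tc$subpulse_us * 1e-6,
             blip_duration = tc$blip_us * 1e-6, dt = tc$dt_us * 1e-6)
}

.cfg_phantom <- function(cfg) {
  pc <- cfg$phantom
  phantom_config(grid_n = pc$grid_n, fov = pc$fov_mm * 1e-3,
                 n_channels = pc$n_channels, brightening = pc$brightening,
                 gain_jitter = pc$gain_jitter, db0_range = pc$db0_range_hz,
                 seed = cfg$seed)
}

.cfg_limits <- function(cfg) {
  sc <- cfg$safety
  default_limits(sar_10g_max = sc$sar_10g_max, v_max = sc$v_max,
                 p_max = sc$p_max, g_amp_max = sc$g_amp_max_mt_per_m * 1e-3,
                 g_slew_max = sc$g_slew_max,
                 sar_global_max = if (is.null(sc$sar_global_max) ||
                                      is.na(sc$sar_global_max)) NA_real_
                                  else sc$sar_global_max)
}

# design both flip-angle pulses of one type
.design_pair <- function(type, setup, safety, timing, cfg, log = message) {
  dc <- cfg$design
  lapply(seq_along(dc$alpha_des_deg), function(i) {
    ad <- deg2rad(dc$alpha_des_deg[i])
    t0 <- Sys.time()
    res <- switch(type,
      cp = cp_pulse(setup, ad, timing, safety = safety),
      shim = rf_shim_mls(setup, ad, timing, seed = cfg$seed + i,
                         safety = safety),
      fa = hybrid_design(setup, safety,
             design_spec(alpha_des = ad, beta_des = 0, lambda = 0,
                         n_starts = dc$n_starts, seed = cfg$seed + i,
                         n_clusters = dc$n_clusters), timing),
      hy = {
        bd <- if (!is.null(dc$beta_des_ut)) dc$beta_des_ut[i] else
          1.2 * beta_min(ad, kt_shape_factors(timing), timing)
        hybrid_design(setup, safety,
          design_spec(alpha_des = ad, beta_des = bd, lambda = dc$lambda,
                      n_starts = dc$n_starts, seed = cfg$seed + i,
                      n_clusters = dc$n_clusters), timing)
      },
      .stopf("unknown pulse type '%s'", type))
    log(sprintf("[design:%s] alpha_des=%g deg done in %.1f s (NRMSE_a=%.4f)",
                type, dc$alpha_des_deg[i],
                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                res$nrmse_alpha))
    res
  })
}

#' Run the full phantom-to-R1 experiment
#'
#' Desk-scale analog of the in vivo protocol: generate the phantom and the
#' SAR model, design both flip-angle pulses for each requested pulse type,
#' simulate the two SPGR acquisitions with the two-pool model, fit R1
#' voxelwise, and assemble report tables. Fully deterministic for a fixed
#' seed; stage failures abort with a stage-tagged error.
#'
#' @param config A [experiment_config()].
#' @param out_dir Optional directory; if given, CSV tables, NIfTI maps and
#'   JSON pulses are written there (sufficient to resume any later stage).
#' @param quiet Suppress stage logging.
#' @return A list of class `ptx_experiment` with `designs`, `r1`,
#'   `tables`, `phantom`, `safety`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "ptx_config"))
  log <- if (quiet) function(...) invisible() else message
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      .stopf("[stage:%s] %s", name, conditionMessage(e)))
    log(sprintf("[%s] %.1f s", name, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  ph <- stage("phantom", generate_phantom(.cfg_phantom(config)))
  timing <- .cfg_timing(config)
  safety <- stage("safety", generate_safety_model(
    ph$setup, timing, n_vop = config$safety$n_vop, seed = config$seed,
    sar_fraction = config$safety$sar_fraction, limits = .cfg_limits(config)))
  types <- config$report$pulse_types
  designs <- lapply(stats::setNames(types, types), function(ty)
    stage(paste0("design:", ty),
          .design_pair(ty, ph$setup, safety, timing, config, log)))
  r1 <- lapply(stats::setNames(types, types), function(ty)
    stage(paste0("fit:", ty),
          r1_map_pipeline(ph$setup, ph$tissue, designs[[ty]],
                          tr = timing$tr,
                          noise_sd = config$simulation$noise_sd,
                          seed = config$seed)))
  tables <- report_tables(designs, r1)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_setup(ph$setup, file.path(out_dir, "phantom"))
    write_safety(safety, file.path(out_dir, "safety.json"))
    for (ty in types) {
      for (i in seq_along(designs[[ty]]))
        write_design(designs[[ty]][[i]], ph$setup,
                     file.path(out_dir, sprintf("design_%s_fa%d", ty, i)))
      .write_vol(ph$setup, r1[[ty]]$r1, file.path(out_dir, sprintf("r1_%s.nii.gz", ty)))
    }
    utils::write.csv(tables$tissue, file.path(out_dir, "r1_by_tissue.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$design, file.path(out_dir, "design_metrics.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  structure(list(designs = designs, r1 = r1, tables = tables,
                 phantom = ph, safety = safety, config = config),
            class = "ptx_experiment")
}

#' Assemble report tables from designs and R1 results
#'
#' @param designs Named list (per pulse type) of lists of `ptx_design`.
#' @param r1 Named list (per pulse type) of `ptx_r1map`.
#' @return A list with `design` (per-pulse metrics incl. SAR margins) and
#'   `tissue` (per-type per-tissue R1 mean/SD/CoV) tibbles.
#' @export
report_tables <- function(designs, r1) {
  if (!length(r1)) .stopf("empty input")
  dtab <- do.call(rbind, lapply(names(designs), function(ty)
    do.call(rbind, lapply(designs[[ty]], function(d)
      cbind(tibble::tibble(type = ty), design_summary(d))))))
  ttab <- do.call(rbind, lapply(names(r1), function(ty)
    cbind(tibble::tibble(type = ty), r1[[ty]]$summary)))
  list(design = tibble::as_tibble(dtab), tissue = tibble::as_tibble(ttab))
}

#' Human-readable experiment report
#'
#' Prints per-pulse NRMSE and SAR margins, the per-tissue R1 table, and a
#' CoV comparison across pulse types, flagging any constraint violation.
#' All numbers are recomputed from the stored results.
#'
#' @param experiment A `ptx_experiment` from [run_experiment()].
#' @return The table list, invisibly.
#' @export
report <- function(experiment) {
  stopifnot(inherits(experiment, "ptx_experiment"))
  tabs <- experiment$tables
  cat("== Pulse design metrics ==\n")
  print(as.data.frame(tabs$design), row.names = FALSE, digits = 4)
  if (any(!tabs$design$feasible))
    cat("WARNING: some designs violate operational constraints\n")
  cat("\n== R1 by tissue ==\n")
  print(as.data.frame(tabs$tissue), row.names = FALSE, digits = 4)
  wm <- tabs$tissue[tabs$tissue$label == "WM", c("type", "cov")]
  if (nrow(wm) > 1) {
    cat("\n== WM R1 CoV by pulse type ==\n")
    print(as.data.frame(wm), row.names = FALSE, digits = 4)
  }
  invisible(tabs)
}

#' @export
print.ptx_experiment <- function(x, ...) {
  cat(sprintf("pTx R1-mapping experiment: pulse types %s, seed %d\n",
              paste(names(x$r1), collapse = ", "), x$config$seed))
  report(x)
  invisible(x)
}
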