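#' Plot a mid-volume slice of a per-voxel map
#'
#' @param setup A `ptx_setup`. @param values Full-grid per-voxel vector.
#' @param slice Index along the third axis (default: middle).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(setup, values, slice = NULL, title = NULL) {
  arr <- as_volume(setup, values)
  if (is.null(slice)) slice <- ceiling(setup$grid_n[3] / 2)
  sl <- arr[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a design sweep
#'
#' Flip-angle vs. B1rms NRMSE trade-off curves per B1rms target, with the
#' per-target Pareto-optimal points highlighted.
#'
#' @param object A `ptx_sweep` from [pareto_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ptx_sweep
#' @export
autoplot.ptx_sweep <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[is.finite(df$nrmse_beta), ]
  df$beta_des_f <- factor(signif(df$beta_des, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nrmse_beta, y = .data$nrmse_alpha,
                                   colour = .data$beta_des_f)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = df[df$pareto, ], size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "NRMSE(B1rms)", y = "NRMSE(flip angle)",
                  colour = "beta_des (uT)") +
    ggplot2::theme_minimal()
}
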