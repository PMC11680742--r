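#' Proton gyromagnetic ratio
#'
#' `gamma_1h()` returns the proton gyromagnetic ratio in rad s^-1 T^-1.
#' All field quantities in the package are expressed in microtesla at the
#' user surface and converted with this constant internally.
#'
#' @return A scalar, 2.6752218744e8 rad s^-1 T^-1.
#' @export
gamma_1h <- function() 2.6752218744e8

# muT -> T
.UT <- 1e-6

#' Convert degrees to radians
#' @param deg Angle(s) in degrees.
#' @return Angle(s) in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Convert radians to degrees
#' @param rad Angle(s) in radians.
#' @return Angle(s) in degrees.
#' @export
rad2deg <- function(rad) rad * 180 / pi

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0", name)
  invisible(x)
}

# deterministic RNG scoping: run expr with a local seed, restore RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# weighted L2 norm
.wnorm <- function(x, w) sqrt(sum(w * Mod(x)^2))

#' Weighted normalized root-mean-square error
#'
#' NRMSE of a map against a scalar (or per-voxel) target:
#' \deqn{\mathrm{NRMSE} = \|x - x_{des}\|_W / \|x_{des}\|_W}
#' with \eqn{\|v\|_W = \sqrt{\sum_m W_m v_m^2}}. This is the square root of
#' the normalized mean squared error terms entering the hybrid design cost;
#' reports and sweeps quote this square-root form.
#'
#' @param x Numeric vector of achieved per-voxel values.
#' @param x_des Target: scalar or vector of `length(x)`.
#' @param w Nonnegative weights, same length as `x`.
#' @return Dimensionless scalar, 0 when `x` equals the target everywhere.
#' @export
nrmse <- function(x, x_des, w = rep(1, length(x))) {
  if (length(x_des) == 1L) x_des <- rep(x_des, length(x))
  stopifnot(length(x) == length(x_des), length(w) == length(x))
  denom <- .wnorm(x_des, w)
  if (denom <= 0) .stopf("nrmse: target has zero weighted norm")
  .wnorm(x - x_des, w) / denom
}

#' Coefficient of variation within a mask
#'
#' SD/mean of map values, a scale-invariant spatial-uniformity metric used
#' to compare R1 maps produced by different pulse types.
#'
#' @param map Numeric array or vector.
#' @param mask Logical array/vector selecting the voxels to summarize
#'   (default: all finite values).
#' @return SD divided by mean (dimensionless).
#' @export
cov_metric <- function(map, mask = NULL) {
  x <- as.vector(map)
  if (!is.null(mask)) x <- x[as.vector(mask)]
  x <- x[is.finite(x)]
  if (length(x) < 2L) .stopf("cov_metric: need at least 2 finite values")
  m <- mean(x)
  if (m <= 0) .stopf("cov_metric: mean must be > 0")
  stats::sd(x) / m
}

# complex matrix <-> [re, im] nested lists for JSON round-trips
.cplx_to_json <- function(m) {
  lapply(seq_len(nrow(m)), function(i)
    lapply(seq_len(ncol(m)), function(j) c(Re(m[i, j]), Im(m[i, j]))))
}

.json_to_cplx <- function(lst) {
  n <- length(lst); p <- length(lst[[1]])
  m <- matrix(0i, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    v <- unlist(lst[[i]][[j]])
    m[i, j] <- complex(real = v[1], imaginary = v[2])
  }
  m
}
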