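#' Design specification for the hybrid optimization
#'
#' Targets and solver settings for the dual-cost pulse design: a scalar
#' flip-angle target `alpha_des` (radians), a scalar B1rms target
#' `beta_des` (microtesla), and the balancing weight `lambda` in \[0, 1\]
#' (`0` = flip-angle-only design, `1` = B1rms-only / saturation design).
#'
#' @param alpha_des Target flip angle, radians.
#' @param beta_des Target B1rms, microtesla (>= 0).
#' @param lambda Balance weight in \[0, 1\].
#' @param n_starts Number of random multi-start initializations (>= 1).
#' @param seed Integer seed controlling all starts.
#' @param n_clusters Voxel-compression cluster count (0 disables).
#' @param control Solver control list passed to the augmented-Lagrangian
#'   loop (see internals); sensible defaults if empty.
#' @return A list of class `ptx_design_spec`.
#' @export
design_spec <- function(alpha_des = deg2rad(15), beta_des = 0, lambda = 0.5,
                        n_starts = 10L, seed = 1L, n_clusters = 500L,
                        control = list()) {
  if (lambda < 0 || lambda > 1) .stopf("lambda must be in [0, 1]")
  if (beta_des < 0) .stopf("beta_des must be >= 0")
  if (n_starts < 1) .stopf("n_starts must be >= 1")
  structure(list(alpha_des = alpha_des, beta_des = beta_des, lambda = lambda,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 n_clusters = as.integer(n_clusters), control = control),
            class = "ptx_design_spec")
}

# ---- parameter packing -----------------------------------------------------
# x = [Re(vec(b)), Im(vec(b)), vec(g)]; b is Nch x n_sub volts, g is
# (n_sub-1) x 3 blip moments in rad/m.

.pack_x <- function(b, g) c(Re(b), Im(b), as.numeric(g))

.unpack_x <- function(x, nch, nsub) {
  nb <- nch * nsub
  b <- matrix(complex(real = x[seq_len(nb)], imaginary = x[nb + seq_len(nb)]),
              nch, nsub)
  g <- matrix(x[2 * nb + seq_len(3 * (nsub - 1))], nsub - 1L, 3L)
  list(b = b, g = g)
}

#' Build the hybrid design objective with analytic gradient
#'
#' Returns the squared-NRMSE dual cost
#' \deqn{f(b, g) = (1-\lambda)\,\mathrm{NRMSE}_\alpha^2 + \lambda\,\mathrm{NRMSE}_\beta^2}
#' as a function of the packed real parameter vector (RF real/imaginary
#' parts followed by blip moments), together with its analytic gradient.
#' Exposed so gradient correctness can be verified against finite
#' differences and so callers can plug the objective into other solvers.
#'
#' @param setup A `ptx_setup` (typically cluster-compressed).
#' @param timing A [seq_timing()].
#' @param alpha_des,beta_des,lambda Targets and balance as in
#'   [design_spec()].
#' @return A list with `fn(x)`, `gr(x)`, `n_par`, `nch`, `nsub`, and
#'   `maps(x)` returning the per-voxel alpha/beta of the current iterate.
#' @export
make_design_objective <- function(setup, timing, alpha_des, beta_des, lambda) {
  vox <- which(setup$mask)
  S <- setup$sens[vox, , drop = FALSE]          # Ns x Nch, muT/V
  W <- setup$weights[vox]
  r <- setup$coords[vox, , drop = FALSE]
  nch <- setup$n_channels
  nsub <- timing$n_subpulses
  # off-resonance factor summed within each subpulse: Ns x nsub
  ph <- exp(1i * outer(2 * pi * setup$db0[vox], timing$t - timing$tau))
  ind <- outer(timing$subpulse_of, seq_len(nsub), "==") * 1   # Nt x nsub
  OffR <- ph %*% ind                             # Ns x nsub
  cA <- gamma_1h() * timing$dt * .UT / setup$m0  # rad per (muT/V * V) sample
  kb <- timing$subpulse_duration / timing$tr     # B1rms duty factor
  Na <- sum(W) * alpha_des^2
  Nb <- if (beta_des > 0) sum(W) * beta_des^2 else 1
  use_a <- lambda < 1
  use_b <- lambda > 0
  n_par <- 2 * nch * nsub + 3 * (nsub - 1L)

  eval_all <- function(x, want_grad = TRUE) {
    u <- .unpack_x(x, nch, nsub)
    b <- u$b; g <- u$g
    kj <- .subpulse_kspace(g, nsub)
    C <- OffR * exp(1i * tcrossprod(r, kj))      # Ns x nsub
    F <- S %*% b                                 # Ns x nsub, muT
    Tm <- (1i * cA) * (C * F)                    # per-subpulse STA contribution
    m <- rowSums(Tm)
    alpha <- Mod(m)
    beta <- sqrt(kb * rowSums(Mod(F)^2))
    val <- 0
    gb <- matrix(0i, nch, nsub)
    gg <- matrix(0, max(nsub - 1L, 0L), 3L)
    if (use_a) {
      fa <- sum(W * (alpha - alpha_des)^2) / Na
      val <- val + (1 - lambda) * fa
      if (want_grad) {
        asafe <- pmax(alpha, 1e-300)
        cm <- (1 - lambda) * 2 * W * (alpha - alpha_des) / (Na * asafe)
        v <- cm * Conj(m)
        gb <- gb + (1i * cA) * crossprod(S, v * C)      # Nch x nsub
        if (nsub > 1L) {
          Mpart <- t(apply(Tm, 1, cumsum))
          if (nsub == 1L) Mpart <- matrix(Mpart, ncol = 1)
          Z <- Im(v * Mpart[, seq_len(nsub - 1L), drop = FALSE])
          gg <- gg + crossprod(Z, r)
        }
      }
    }
    if (use_b) {
      fb <- sum(W * (beta - beta_des)^2) / Nb
      val <- val + lambda * fb
      if (want_grad) {
        bsafe <- pmax(beta, 1e-12)
        em <- lambda * 2 * W * (beta - beta_des) / (Nb * bsafe) * kb
        gb <- gb + crossprod(S, em * Conj(F))
      }
    }
    list(value = val, gb = gb, gg = gg, alpha = alpha, beta = beta)
  }

  list(
    fn = function(x) eval_all(x, want_grad = FALSE)$value,
    gr = function(x) {
      e <- eval_all(x, want_grad = TRUE)
      # d/dRe b = Re(gb), d/dIm b = -Im(gb) under the conj(m) convention
      c(Re(e$gb), -Im(e$gb), as.numeric(e$gg))
    },
    maps = function(x) {
      e <- eval_all(x, want_grad = FALSE)
      list(alpha = e$alpha, beta = e$beta)
    },
    n_par = n_par, nch = nch, nsub = nsub
  )
}

# ---- constraint set (normalized, with analytic Jacobian) -------------------

make_constraint_set <- function(safety, timing, nch, nsub) {
  lim <- safety$limits
  kb <- timing$subpulse_duration / timing$tr
  nb <- nch * nsub
  vops <- safety$vops
  use_glob <- is.finite(lim$sar_global_max)
  n_par <- 2 * nb + 3 * (nsub - 1L)

  cfun <- function(x) {
    u <- .unpack_x(x, nch, nsub)
    b <- u$b
    v2 <- Mod(b)^2
    cV <- as.numeric(v2) / lim$v_max^2 - 1
    cP <- kb * rowSums(v2) / 100 / lim$p_max - 1
    cS <- vapply(vops, function(Q)
      kb * sum(Re(Conj(b) * (Q %*% b))) / lim$sar_10g_max - 1, numeric(1))
    out <- c(cV, cP, cS)
    if (use_glob)
      out <- c(out, kb * sum(Re(Conj(b) * (safety$q_global %*% b))) /
                 lim$sar_global_max - 1)
    out
  }
  jfun <- function(x) {
    u <- .unpack_x(x, nch, nsub)
    b <- u$b
    nv <- nb
    ncon <- nv + nch + length(vops) + as.integer(use_glob)
    J <- matrix(0, ncon, n_par)
    # voltage: c_{qj} = (Re^2+Im^2)/Vmax^2 - 1
    idx <- seq_len(nv)
    J[cbind(idx, idx)] <- 2 * Re(as.vector(b)) / lim$v_max^2
    J[cbind(idx, nb + idx)] <- 2 * Im(as.vector(b)) / lim$v_max^2
    # power per channel
    for (q in seq_len(nch)) {
      cols <- q + nch * (seq_len(nsub) - 1L)
      J[nv + q, cols] <- 2 * kb * Re(b[q, ]) / 100 / lim$p_max
      J[nv + q, nb + cols] <- 2 * kb * Im(b[q, ]) / 100 / lim$p_max
    }
    # local SAR per VOP
    for (v in seq_along(vops)) {
      Qb <- vops[[v]] %*% b                     # Nch x nsub
      J[nv + nch + v, seq_len(nb)] <- 2 * kb * Re(as.vector(Qb)) / lim$sar_10g_max
      J[nv + nch + v, nb + seq_len(nb)] <- 2 * kb * Im(as.vector(Qb)) / lim$sar_10g_max
    }
    if (use_glob) {
      Qb <- safety$q_global %*% b
      J[ncon, seq_len(nb)] <- 2 * kb * Re(as.vector(Qb)) / lim$sar_global_max
      J[ncon, nb + seq_len(nb)] <- 2 * kb * Im(as.vector(Qb)) / lim$sar_global_max
    }
    J
  }
  list(hin = cfun, hin_jac = jfun)
}

# ---- DesignResult ----------------------------------------------------------

.design_result <- function(pulse, setup, safety, lambda, alpha_des, beta_des,
                           start_costs = numeric(0), start_index = 1L,
                           converged = TRUE, mode = "hybrid") {
  vox <- which(setup$mask)
  alpha <- flip_angle_map(pulse, setup, voxels = vox)
  beta <- b1rms_map(pulse, setup, voxels = vox)
  w <- setup$weights[vox]
  na <- nrmse(alpha, alpha_des, w)
  nb <- if (beta_des > 0) nrmse(beta, beta_des, w) else NA_real_
  cost <- (1 - lambda) * na^2 + if (lambda > 0) lambda * nb^2 else 0
  full_a <- rep(NA_real_, prod(setup$grid_n)); full_a[vox] <- alpha
  full_b <- rep(NA_real_, prod(setup$grid_n)); full_b[vox] <- beta
  cons <- if (!is.null(safety)) check_constraints(pulse, safety) else NULL
  structure(list(
    pulse = pulse, alpha_map = full_a, beta_map = full_b,
    nrmse_alpha = na, nrmse_beta = nb, cost = cost,
    lambda = lambda, alpha_des = alpha_des, beta_des = beta_des,
    constraints = cons, start_costs = start_costs, start_index = start_index,
    converged = converged, mode = mode, grid_n = setup$grid_n,
    mask = setup$mask
  ), class = "ptx_design")
}

#' @export
print.ptx_design <- function(x, ...) {
  cat(sprintf("%s pulse design: NRMSE(alpha) = %.4f%s, cost = %.3e%s\n",
              toupper(x$mode), x$nrmse_alpha,
              if (is.finite(x$nrmse_beta)) sprintf(", NRMSE(beta) = %.4f", x$nrmse_beta) else "",
              x$cost,
              if (!is.null(x$constraints) && !x$constraints$all_satisfied) " [constraints VIOLATED]" else ""))
  invisible(x)
}

#' Tidy one-row summary of a design result
#'
#' @param result A `ptx_design`.
#' @return A one-row tibble with targets, errors, cost and SAR margins.
#' @export
design_summary <- function(result) {
  stopifnot(inherits(result, "ptx_design"))
  m <- result$constraints$margins
  tibble::tibble(
    mode = result$mode, lambda = result$lambda,
    alpha_des_deg = rad2deg(result$alpha_des), beta_des = result$beta_des,
    nrmse_alpha = result$nrmse_alpha, nrmse_beta = result$nrmse_beta,
    cost = result$cost,
    sar_local = result$constraints$sar_local_max,
    margin_sar = unname(m["sar_local"]), margin_voltage = unname(m["voltage"]),
    margin_power = unname(m["power"]),
    converged = result$converged,
    feasible = result$constraints$all_satisfied
  )
}

# ---- baseline designs ------------------------------------------------------

#' CP-mode pulse with least-squares amplitude
#'
#' Single 200 us rectangular pulse played with fixed circularly polarized
#' channel weights; the one real amplitude is the closed-form minimizer of
#' the weighted flip-angle MSE,
#' \eqn{c^* = \sum_m W_m a_m \alpha_{des} / \sum_m W_m a_m^2},
#' where `a_m` is the per-volt flip angle of the CP combination.
#'
#' @param setup A `ptx_setup`.
#' @param alpha_des Target flip angle, radians.
#' @param timing A [seq_timing()]; only TR and the subpulse duration are
#'   used (the CP pulse is a single subpulse).
#' @param safety Optional `ptx_safety` for the constraint report.
#' @return A `ptx_design` result.
#' @export
cp_pulse <- function(setup, alpha_des, timing = seq_timing(), safety = NULL) {
  tm1 <- seq_timing(tr = timing$tr, n_subpulses = 1L,
                    subpulse_duration = timing$subpulse_duration,
                    dt = timing$dt)
  w <- cp_weights(setup$n_channels)
  a_unit <- flip_angle_map(kt_pulse(matrix(w, ncol = 1), timing = tm1), setup)
  if (max(a_unit) <= 0) .stopf("CP combined field is zero everywhere")
  wts <- setup$weights[setup$mask]
  c_star <- sum(wts * a_unit * alpha_des) / sum(wts * a_unit^2)
  pulse <- kt_pulse(matrix(w * c_star, ncol = 1), timing = tm1)
  res <- .design_result(pulse, setup, safety, lambda = 0,
                        alpha_des = alpha_des, beta_des = 0, mode = "cp")
  res$amplitude <- c_star
  res
}

#' Magnitude-least-squares RF shim
#'
#' Static per-channel complex weights for a single rectangular subpulse,
#' fitted to the flip-angle magnitude target by variable-exchange
#' iteration: alternately fix the target phase to the current field phase
#' and solve the weighted complex least-squares problem. The first start is
#' the CP solution (so the result can never be worse than CP mode); the
#' remaining starts use random phases.
#'
#' @inheritParams cp_pulse
#' @param seed Seed for the random starts.
#' @param n_starts Number of starts (first is CP-initialized).
#' @param max_iter Maximum exchange iterations per start.
#' @return A `ptx_design` result; `$trace` holds the per-iteration cost of
#'   the winning start (non-increasing).
#' @export
rf_shim_mls <- function(setup, alpha_des, timing = seq_timing(), seed = 1L,
                        n_starts = 5L, max_iter = 60L, safety = NULL) {
  tm1 <- seq_timing(tr = timing$tr, n_subpulses = 1L,
                    subpulse_duration = timing$subpulse_duration,
                    dt = timing$dt)
  vox <- which(setup$mask)
  nch <- setup$n_channels
  # per-volt complex flip contribution of each channel (Ns x Nch)
  A1 <- system_matrix(setup, tm1, matrix(0, tm1$n_samples, 3), vox)
  Fm <- (setup$sens[vox, , drop = FALSE] * .UT) * rowSums(A1)
  W <- setup$weights[vox]
  sw <- sqrt(W)
  cp0 <- cp_pulse(setup, alpha_des, timing)
  best <- NULL
  runs <- with_seed(seed + 17L, {
    lapply(seq_len(n_starts), function(s) {
      w0 <- if (s == 1L) cp0$pulse$rf[, 1] else
        Mod(cp0$pulse$rf[1, 1]) * exp(1i * stats::runif(nch, 0, 2 * pi))
      w <- w0
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        fld <- as.vector(Fm %*% w)
        cost <- sum(W * (Mod(fld) - alpha_des)^2)
        trace <- c(trace, cost)
        if (it > 1 && trace[it - 1] - cost < 1e-14 * max(1, cost)) break
        z <- alpha_des * exp(1i * Arg(fld))
        w <- qr.solve(sw * Fm, sw * z)
      }
      list(w = w, cost = min(trace), trace = trace)
    })
  })
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  bi <- which.min(costs)
  pulse <- kt_pulse(matrix(runs[[bi]]$w, ncol = 1), timing = tm1)
  res <- .design_result(pulse, setup, safety, lambda = 0,
                        alpha_des = alpha_des, beta_des = 0,
                        start_costs = costs, start_index = bi, mode = "shim")
  res$trace <- runs[[bi]]$trace
  res
}

# ---- voxel compression -----------------------------------------------------

#' Compress a transmit setup by k-means voxel clustering
#'
#' Masked voxels are clustered on the standardized feature vector
#' \[Re s_q, Im s_q (all channels), off-resonance, x, y, z\]; the compressed
#' setup carries one pseudo-voxel per cluster with centroid features and a
#' weight equal to the cluster size, so the weighted design cost on the
#' compressed problem approximates the full-resolution cost. Weights sum
#' to the number of masked voxels.
#'
#' @param setup A `ptx_setup`.
#' @param n_clusters Cluster count (1..number of masked voxels); if equal
#'   to the voxel count the compression is the identity.
#' @param seed Seed for the k-means initialization.
#' @return A list with `setup` (compressed `ptx_setup`) and `index`
#'   (cluster id per masked voxel).
#' @export
cluster_compress <- function(setup, n_clusters = 500L, seed = 1L) {
  vox <- which(setup$mask)
  nv <- length(vox)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) .stopf("n_clusters must be >= 1")
  if (n_clusters > nv) .stopf("n_clusters exceeds the number of masked voxels")
  feats <- cbind(Re(setup$sens[vox, , drop = FALSE]),
                 Im(setup$sens[vox, , drop = FALSE]),
                 setup$db0[vox], setup$coords[vox, , drop = FALSE])
  if (n_clusters == nv) {
    cl <- seq_len(nv)
  } else {
    sdv <- apply(feats, 2, stats::sd)
    sdv[sdv == 0] <- 1
    std <- sweep(feats, 2, sdv, "/")
    cl <- with_seed(seed + 101L, {
      stats::kmeans(std, centers = n_clusters, iter.max = 100L,
                    nstart = 1L)$cluster
    })
  }
  size <- as.vector(table(factor(cl, levels = seq_len(n_clusters))))
  cent <- unname(rowsum(feats, cl)) / size
  nch <- setup$n_channels
  sens_c <- matrix(complex(real = cent[, seq_len(nch)],
                           imaginary = cent[, nch + seq_len(nch)]),
                   n_clusters, nch)
  comp <- structure(list(
    grid_n = c(n_clusters, 1L, 1L), fov = setup$fov,
    coords = cent[, 2 * nch + 1 + (1:3), drop = FALSE],
    sens = sens_c, db0 = cent[, 2 * nch + 1],
    mask = rep(TRUE, n_clusters), weights = size,
    m0 = setup$m0, n_channels = nch, config = setup$config
  ), class = "ptx_setup")
  list(setup = comp, index = cl)
}

# ---- hybrid design ---------------------------------------------------------

#' Hybrid flip-angle / B1rms constrained pulse design
#'
#' Minimizes the dual cost
#' \eqn{(1-\lambda)\,\mathrm{NRMSE}_\alpha^2 + \lambda\,\mathrm{NRMSE}_\beta^2}
#' over per-channel complex subpulse amplitudes and gradient-blip moments,
#' subject to local (VOP) and optional global SAR, per-channel average
#' power, per-channel peak voltage, and box bounds on the blip moments
#' (which exactly replace the waveform-level gradient amplitude/slew
#' limits for triangular blips). Solved by multi-start augmented
#' Lagrangian with analytic gradients; the best feasible start wins (ties
#' broken by lower local SAR). Reported maps and errors are recomputed on
#' the full, uncompressed setup.
#'
#' `lambda = 0` reproduces a pure flip-angle design; `lambda = 1` a pure
#' B1rms (saturation-homogeneity) design. For `lambda` strictly inside
#' (0, 1) a `beta_des` below the [beta_min()] bound makes the two targets
#' inconsistent; the design proceeds but warns.
#'
#' @param setup A `ptx_setup` (full resolution).
#' @param safety A `ptx_safety` model.
#' @param spec A [design_spec()].
#' @param timing A [seq_timing()].
#' @return A `ptx_design` result.
#' @export
hybrid_design <- function(setup, safety, spec = design_spec(),
                          timing = seq_timing()) {
  stopifnot(inherits(spec, "ptx_design_spec"))
  lam <- spec$lambda
  if (lam > 0 && lam < 1 && spec$beta_des > 0) {
    bmin <- beta_min(spec$alpha_des, kt_shape_factors(timing), timing)
    if (spec$beta_des < bmin * (1 - 1e-9))
      warning(sprintf("beta_des (%.3g uT) below the beta_min bound (%.3g uT); targets are inconsistent",
                      spec$beta_des, bmin), call. = FALSE)
  }
  nvox <- sum(setup$mask)
  dsgn_setup <- setup
  if (spec$n_clusters > 0L && spec$n_clusters < nvox)
    dsgn_setup <- cluster_compress(setup, spec$n_clusters, spec$seed)$setup
  nch <- setup$n_channels
  nsub <- timing$n_subpulses
  obj <- make_design_objective(dsgn_setup, timing, spec$alpha_des,
                               spec$beta_des, lam)
  cons <- make_constraint_set(safety, timing, nch, nsub)
  dkmax <- max_blip_moment(timing$blip_duration, safety$limits$g_amp_max,
                           safety$limits$g_slew_max)
  nb <- nch * nsub
  lower <- c(rep(-Inf, 2 * nb), rep(-dkmax, 3 * (nsub - 1L)))
  upper <- c(rep(Inf, 2 * nb), rep(dkmax, 3 * (nsub - 1L)))

  # least-squares scale so a random start lands near alpha_des
  scale_to_target <- function(b, g) {
    a1 <- obj$maps(.pack_x(b, g))$alpha
    w <- dsgn_setup$weights[dsgn_setup$mask]
    s <- sum(w * a1 * spec$alpha_des) / max(sum(w * a1^2), 1e-300)
    b * s
  }

  runs <- lapply(seq_len(spec$n_starts), function(s) {
    init <- with_seed(spec$seed + 131L * s, {
      b0 <- matrix(complex(real = stats::rnorm(nb), imaginary = stats::rnorm(nb)),
                   nch, nsub)
      g0 <- if (nsub > 1L)
        matrix(stats::runif(3 * (nsub - 1L), -0.2 * dkmax, 0.2 * dkmax),
               nsub - 1L, 3L) else matrix(0, 0, 3)
      list(b = b0, g = g0)
    })
    b0 <- scale_to_target(init$b, init$g)
    x0 <- .pack_x(b0, init$g)
    sol <- auglag_solve(x0, obj$fn, obj$gr, cons$hin, cons$hin_jac,
                        lower = lower, upper = upper, control = spec$control)
    sol
  })
  costs <- vapply(runs, `[[`, numeric(1), "value")
  feas <- vapply(runs, `[[`, logical(1), "feasible")
  # best feasible by cost; ties (within 1e-12) broken by lower local SAR
  cand <- if (any(feas)) which(feas) else seq_along(runs)
  ord <- cand[order(costs[cand])]
  pick <- ord[1]
  if (length(ord) > 1) {
    tied <- ord[costs[ord] <= costs[pick] + 1e-12]
    if (length(tied) > 1) {
      sar <- vapply(tied, function(i) {
        u <- .unpack_x(runs[[i]]$par, nch, nsub)
        local_sar(kt_pulse(u$b, u$g, timing), safety)$max
      }, numeric(1))
      pick <- tied[which.min(sar)]
    }
  }
  u <- .unpack_x(runs[[pick]]$par, nch, nsub)
  pulse <- kt_pulse(u$b, u$g, timing)
  res <- .design_result(pulse, setup, safety, lam, spec$alpha_des,
                        spec$beta_des, start_costs = costs,
                        start_index = pick,
                        converged = any(feas),
                        mode = if (lam == 0) "fa" else if (lam == 1) "push" else "hybrid")
  res$compressed_cost <- costs[pick]
  res
}

# ---- sweep drivers ---------------------------------------------------------

#' Log-spaced lambda grid, denser at the bounds
#'
#' Builds a grid on \[0, 1\] containing the endpoints exactly, with the
#' interior points log-spaced toward both bounds (sparser in the middle),
#' mirroring how the balance parameter is swept.
#'
#' @param n Number of grid points (>= 2).
#' @param eps Smallest interior offset from the bounds.
#' @return Sorted numeric vector of length `n` with `0` and `1` included.
#' @export
lambda_grid <- function(n = 51L, eps = 1e-3) {
  n <- as.integer(n)
  if (n < 2L) .stopf("n must be >= 2")
  m <- n - 2L
  interior <- if (m <= 0L) numeric(0) else {
    h <- m %/% 2L
    left <- if (h > 0L) exp(seq(log(eps), log(0.5), length.out = h + 1L))[seq_len(h)]
            else numeric(0)
    mid <- if (m %% 2L == 1L) 0.5 else numeric(0)
    c(left, mid, 1 - left)
  }
  sort(unique(c(0, interior, 1)))
}

#' Sweep the design over B1rms targets and balance weights
#'
#' Runs [hybrid_design()] over the Cartesian grid of `beta_grid` (uT) and
#' `lambda_grid` values, collecting per-point NRMSEs, cost, and SAR
#' margins, and flagging the per-`beta_des` Pareto-optimal points in the
#' (NRMSE_alpha, NRMSE_beta) plane. Deterministic for a fixed seed.
#'
#' @param setup,safety,timing As in [hybrid_design()].
#' @param alpha_des Target flip angle, radians.
#' @param beta_grid Numeric vector of B1rms targets, microtesla.
#' @param lambdas Numeric vector of balance weights in \[0, 1\].
#' @param seed,n_starts,n_clusters,control Passed to [design_spec()].
#' @return A tibble of class `ptx_sweep`, one row per grid point.
#' @export
pareto_sweep <- function(setup, safety, alpha_des, beta_grid,
                         lambdas = lambda_grid(7), timing = seq_timing(),
                         seed = 1L, n_starts = 5L, n_clusters = 500L,
                         control = list()) {
  if (!length(beta_grid) || !length(lambdas)) .stopf("grids must be non-empty")
  rows <- list()
  for (bd in beta_grid) for (lam in lambdas) {
    sp <- design_spec(alpha_des = alpha_des, beta_des = bd, lambda = lam,
                      n_starts = n_starts, seed = seed,
                      n_clusters = n_clusters, control = control)
    res <- suppressWarnings(hybrid_design(setup, safety, sp, timing))
    rows[[length(rows) + 1L]] <- cbind(design_summary(res),
                                       tibble::tibble(beta_des_in = bd))
  }
  tab <- tibble::as_tibble(do.call(rbind, rows))
  tab$beta_des <- tab$beta_des_in
  tab$beta_des_in <- NULL
  # Pareto flag per beta_des (beta NRMSE undefined when beta_des = 0)
  tab$pareto <- FALSE
  for (bd in unique(tab$beta_des)) {
    ii <- which(tab$beta_des == bd & is.finite(tab$nrmse_beta))
    for (i in ii) {
      dom <- any(tab$nrmse_alpha[ii] <= tab$nrmse_alpha[i] &
                 tab$nrmse_beta[ii] <= tab$nrmse_beta[i] &
                 (tab$nrmse_alpha[ii] < tab$nrmse_alpha[i] |
                  tab$nrmse_beta[ii] < tab$nrmse_beta[i]))
      tab$pareto[i] <- !dom
    }
  }
  class(tab) <- c("ptx_sweep", class(tab))
  tab
}
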