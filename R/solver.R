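# Augmented-Lagrangian solver for smooth inequality-constrained problems.
#
# minimize f(x)  s.t.  c_i(x) <= 0,  lower <= x <= upper
#
# Classic PHR augmented Lagrangian with an L-BFGS-B inner solver; both the
# objective and the constraints supply analytic gradients. Used by the
# hybrid pulse design, where c_i are the (normalized) SAR, power and
# voltage constraints and the box bounds hold the blip moments.

auglag_solve <- function(x0, fn, gr, hin = NULL, hin_jac = NULL,
                         lower = -Inf, upper = Inf,
                         control = list()) {
  ctrl <- utils::modifyList(list(
    outer_iter = 8L, inner_maxit = 80L, rho0 = 10, rho_growth = 5,
    tol_feas = 1e-7, tol_f = 1e-10, factr = 1e7
  ), control)
  has_con <- !is.null(hin)
  mu <- if (has_con) rep(0, length(hin(x0))) else numeric(0)
  rho <- ctrl$rho0
  x <- x0
  viol_prev <- Inf
  f_prev <- Inf
  for (it in seq_len(ctrl$outer_iter)) {
    lag <- function(z) {
      v <- fn(z)
      if (has_con) {
        cc <- hin(z)
        s <- pmax(0, mu + rho * cc)
        v <- v + sum(s^2 - mu^2) / (2 * rho)
      }
      v
    }
    lag_gr <- function(z) {
      g <- gr(z)
      if (has_con) {
        cc <- hin(z)
        s <- pmax(0, mu + rho * cc)
        act <- s > 0
        if (any(act)) {
          J <- hin_jac(z)
          g <- g + drop(crossprod(J[act, , drop = FALSE], s[act]))
        }
      }
      g
    }
    opt <- stats::optim(x, lag, lag_gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctrl$inner_maxit,
                                       factr = ctrl$factr))
    x <- opt$par
    if (!has_con) {
      conv <- abs(f_prev - opt$value) < ctrl$tol_f * max(1, abs(opt$value))
      f_prev <- opt$value
      if (conv) break
      next
    }
    cc <- hin(x)
    viol <- max(0, max(cc))
    mu <- pmax(0, mu + rho * cc)
    if (viol > ctrl$tol_feas && viol > 0.25 * viol_prev) rho <- rho * ctrl$rho_growth
    f_now <- fn(x)
    if (viol <= ctrl$tol_feas &&
        abs(f_prev - f_now) < ctrl$tol_f * max(1, abs(f_now))) {
      f_prev <- f_now
      break
    }
    f_prev <- f_now
    viol_prev <- viol
  }
  list(par = x, value = fn(x),
       feasible = !has_con || max(hin(x)) <= 1e2 * ctrl$tol_feas,
       max_violation = if (has_con) max(0, max(hin(x))) else 0)
}
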