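test_that("CP pulse amplitude has the weighted least-squares closed form", {
  setup <- small_phantom()$setup
  ad <- deg2rad(15)
  res <- cp_pulse(setup, ad)
  # golden-section oracle on the scalar MSE
  tm1 <- res$pulse$timing
  a_unit <- flip_angle_map(kt_pulse(matrix(cp_weights(8), ncol = 1), timing = tm1),
                           setup)
  w <- setup$weights[setup$mask]
  mse <- function(c) sum(w * (c * a_unit - ad)^2)
  opt <- stats::optimize(mse, c(0, 1e4), tol = 1e-12)
  expect_equal(res$amplitude, opt$minimum, tolerance = 1e-6)
  # uniform field hits the target exactly
  su <- toy_setup(matrix(rep(0.005 + 0i, 8), 4, 8, byrow = TRUE) *
                    matrix(Conj(cp_weights(8)), 4, 8, byrow = TRUE))
  expect_lt(cp_pulse(su, ad)$nrmse_alpha, 1e-12)
  # doubling the sensitivities halves the amplitude
  setup2 <- setup; setup2$sens <- setup$sens * 2
  expect_equal(cp_pulse(setup2, ad)$amplitude, res$amplitude / 2,
               tolerance = 1e-10)
})

test_that("MLS RF shim is monotone and never worse than CP mode", {
  setup <- small_phantom()$setup
  ad <- deg2rad(15)
  shim <- rf_shim_mls(setup, ad, seed = 2L, n_starts = 3L)
  expect_true(all(diff(shim$trace) <= 1e-12))
  cpd <- cp_pulse(setup, ad)
  expect_lte(shim$nrmse_alpha, cpd$nrmse_alpha + 1e-9)
  # one channel: no phase freedom, reduces to the CP amplitude solution
  su1 <- toy_setup(matrix(complex(modulus = runif(6, 2e-3, 8e-3),
                                  argument = runif(6, -pi, pi)), 6, 1))
  s1 <- rf_shim_mls(su1, ad, seed = 1L, n_starts = 2L)
  c1 <- cp_pulse(su1, ad)
  expect_equal(s1$nrmse_alpha, c1$nrmse_alpha, tolerance = 1e-9)
})

test_that("cluster compression conserves weights and is the identity at full size", {
  setup <- small_phantom()$setup
  nv <- sum(setup$mask)
  cc <- cluster_compress(setup, 80L, seed = 3L)
  expect_equal(sum(cc$setup$weights), nv)
  expect_length(cc$index, nv)
  id <- cluster_compress(setup, nv, seed = 3L)
  expect_true(all(id$setup$weights == 1))
  expect_equal(sort(id$setup$db0), sort(setup$db0[setup$mask]))
  expect_error(cluster_compress(setup, 0L), "n_clusters")
  expect_error(cluster_compress(setup, nv + 1L), "exceeds")
})

test_that("design objective gradient matches central finite differences", {
  setup <- cluster_compress(small_phantom()$setup, 60L, seed = 1L)$setup
  tm <- seq_timing()
  obj <- make_design_objective(setup, tm, deg2rad(15), 0.42, 0.5)
  set.seed(21)
  x <- c(rnorm(80) * 20, runif(12, -15, 15))
  ga <- obj$gr(x)
  gn <- fd_grad(obj$fn, x, h = 1e-4)
  expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-5)
})

test_that("a trivially reachable flip-angle target is hit to high precision", {
  su <- toy_setup(matrix(rep(0.008 + 0i, 10), 10, 1))
  saf <- generate_safety_model(su, seed = 5L)
  res <- hybrid_design(su, saf,
                       design_spec(alpha_des = deg2rad(15), beta_des = 0,
                                   lambda = 0, n_starts = 2L, seed = 1L,
                                   n_clusters = 0L))
  expect_lt(res$nrmse_alpha, 1e-6)
})

test_that("lambda = 0 design is identical to a dedicated flip-angle-only objective", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  sp0 <- design_spec(beta_des = 0.415, lambda = 0, n_starts = 2L, seed = 7L,
                     n_clusters = 80L)
  spf <- design_spec(beta_des = 0, lambda = 0, n_starts = 2L, seed = 7L,
                     n_clusters = 80L)
  r0 <- hybrid_design(setup, saf, sp0)
  rf_ <- hybrid_design(setup, saf, spf)
  expect_equal(r0$pulse$rf, rf_$pulse$rf, tolerance = 1e-10)
  expect_equal(r0$cost, rf_$cost, tolerance = 1e-10)
})

test_that("multi-start design is deterministic for a fixed seed", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  sp <- design_spec(beta_des = 0.415, lambda = 0.5, n_starts = 2L, seed = 9L,
                    n_clusters = 80L)
  a <- hybrid_design(setup, saf, sp)
  b <- hybrid_design(setup, saf, sp)
  expect_identical(a$pulse$rf, b$pulse$rf)
  expect_identical(a$start_costs, b$start_costs)
})

test_that("reported cost equals its recomputation from the returned maps", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  res <- hybrid_design(setup, saf,
                       design_spec(beta_des = 0.415, lambda = 0.5,
                                   n_starts = 2L, seed = 3L, n_clusters = 80L))
  w <- setup$weights[setup$mask]
  na <- nrmse(res$alpha_map[setup$mask], res$alpha_des, w)
  nb <- nrmse(res$beta_map[setup$mask], res$beta_des, w)
  expect_equal(res$cost, 0.5 * na^2 + 0.5 * nb^2, tolerance = 1e-12)
  # compression error between cluster-level and full-map cost stays small
  expect_lt(abs(res$cost - res$compressed_cost) / max(res$cost, 1e-12), 0.5)
})

test_that("global RF phase is a gauge freedom of cost and constraints", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  res <- hybrid_design(setup, saf,
                       design_spec(beta_des = 0.415, lambda = 0.5,
                                   n_starts = 1L, seed = 5L, n_clusters = 80L))
  p2 <- kt_pulse(res$pulse$rf * exp(1i * 1.234), res$pulse$blip_moments,
                 res$pulse$timing)
  r2 <- ptxhybrid:::.design_result(p2, setup, saf, 0.5, res$alpha_des,
                                   res$beta_des)
  expect_equal(r2$cost, res$cost, tolerance = 1e-10)
  expect_equal(r2$constraints$sar_local_max, res$constraints$sar_local_max,
               tolerance = 1e-10)
})

test_that("tightening the voltage limit forces a different feasible solution", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  sp <- design_spec(beta_des = 0.415, lambda = 0.5, n_starts = 2L, seed = 13L,
                    n_clusters = 80L)
  res <- hybrid_design(setup, saf, sp)
  vmax0 <- max(Mod(res$pulse$rf))
  saf2 <- saf
  saf2$limits$v_max <- 0.7 * vmax0
  res2 <- hybrid_design(setup, saf2, sp)
  expect_lte(max(Mod(res2$pulse$rf)), saf2$limits$v_max * (1 + 1e-4))
  expect_gt(max(Mod(res2$pulse$rf - res$pulse$rf)), 1e-6)
})

test_that("an inconsistent beta target warns but still runs", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  expect_warning(
    hybrid_design(setup, saf,
                  design_spec(beta_des = 0.1, lambda = 0.5, n_starts = 1L,
                              seed = 1L, n_clusters = 60L)),
    "beta_min")
})

test_that("lambda grid contains exact endpoints and is denser at the bounds", {
  g <- lambda_grid(7, eps = 0.02)
  expect_length(g, 7)
  expect_identical(g[1], 0)
  expect_identical(g[7], 1)
  expect_true(all(diff(g) > 0))
  # denser near the bounds than in the middle
  expect_lt(g[2] - g[1], g[4] - g[3])
  expect_length(lambda_grid(51), 51)
})
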