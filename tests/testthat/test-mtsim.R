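test_that("Bloch simulation reproduces closed-form rotations", {
  su <- toy_setup(matrix(1 + 0i, 1, 1))
  tm <- seq_timing(tr = 8e-3, n_subpulses = 1L, subpulse_duration = 1e-3)
  p90 <- kt_pulse(matrix(5.8716 + 0i, 1, 1), timing = tm)
  expect_equal(rad2deg(bloch_simulate(p90, su)), 90, tolerance = 0.01)
  # zero RF leaves magnetization along +z regardless of off-resonance
  su_off <- toy_setup(matrix(1 + 0i, 1, 1), db0 = 350)
  p0 <- kt_pulse(matrix(0i, 1, 1), timing = tm)
  expect_equal(bloch_simulate(p0, su_off), 0)
})

test_that("Bloch propagator matches the rotation-composition oracle", {
  set.seed(31)
  tm <- seq_timing(tr = 8e-3, n_subpulses = 3L, subpulse_duration = 30e-6,
                   blip_duration = 100e-6, dt = 10e-6)
  for (i in 1:5) {
    su <- toy_setup(matrix(complex(real = rnorm(2), imaginary = rnorm(2)), 1, 2) * 2,
                    db0 = runif(1, -300, 300),
                    coords = matrix(runif(3, -0.1, 0.1), 1, 3))
    p <- kt_pulse(matrix(complex(real = rnorm(6), imaginary = rnorm(6)), 2, 3) * 40,
                  matrix(runif(6, -30, 30), 2, 3), tm)
    expect_equal(bloch_simulate(p, su), bloch_oracle(p, su), tolerance = 1e-10)
  }
})

test_that("small-tip map agrees with Bloch simulation in the small-tip regime", {
  setup <- small_phantom()$setup
  saf <- small_safety()
  res <- hybrid_design(setup, saf,
                       design_spec(alpha_des = deg2rad(15), beta_des = 0.415,
                                   lambda = 0.5, n_starts = 2L, seed = 2L,
                                   n_clusters = 80L))
  a_sta <- res$alpha_map[setup$mask]
  a_bloch <- bloch_simulate(res$pulse, setup)
  rel <- abs(a_sta - a_bloch) / a_bloch
  expect_lt(stats::median(rel), 0.03)
})

test_that("lineshape values, symmetry and limits are correct", {
  expect_equal(lineshape_g(0, 1e-5), 1e-5 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(lineshape_g(0, 1e-5), 3.989e-6, tolerance = 1e-4)
  expect_lt(lineshape_g(1e6, 1e-5), 1e-20)
  d <- c(13.7, 512, 9000)
  expect_equal(lineshape_g(d, 1e-5), lineshape_g(-d, 1e-5))
  # super-Lorentzian: finite on resonance, matches the integral off resonance
  gsl <- lineshape_g(c(0, 5e3), 1e-5, "super-lorentzian")
  expect_true(all(is.finite(gsl) & gsl > 0))
  expect_equal(lineshape_g(2e3, 1e-5, "super-lorentzian"),
               lineshape_g(-2e3, 1e-5, "super-lorentzian"))
  expect_error(lineshape_g(0, 1e-5, "lorentzian"))
})

test_that("apparent R1 has the correct limits, monotonicity and value", {
  wm <- wm_pars()
  r0 <- apparent_r1(0, wm)
  expect_equal(r0, wm$r1f + wm$k_fs * wm$r1s / (wm$r1s + wm$k_sf),
               tolerance = 1e-12)
  expect_equal(apparent_r1(1e5, wm), wm$r1f + wm$k_fs, tolerance = 1e-4)
  bb <- seq(0, 1.5, by = 0.1)
  expect_true(all(diff(apparent_r1(bb, wm)) > 0))
  # frozen direct evaluation of the formula at beta = 0.42 uT
  w <- pi * lineshape_g(0, 1e-5) * (gamma_1h() * 0.42e-6)^2
  manual <- 0.5 + 2 * (1 - wm$k_sf / (3 + wm$k_sf + w))
  expect_equal(apparent_r1(0.42, wm), manual, tolerance = 1e-12)
  expect_equal(manual, 0.88175, tolerance = 1e-4)
  expect_error(apparent_r1(0.4, utils::modifyList(wm, list(k_fs = -1))), "rates")
})

test_that("two-pool SPGR reduces to the Ernst equation without a semisolid pool", {
  pars <- list(r1f = 1 / 1.3, r1s = 3, k_fs = 0, k_sf = 0, m0f = 1, m0s = 0,
               t2s = 1e-5, lineshape = "gaussian")
  a <- deg2rad(seq(1, 40, by = 3))
  tr <- 8e-3
  s <- spgr_two_pool_steady_state(a, 0.5, pars, tr)
  E1 <- exp(-tr / 1.3)
  expect_equal(s, sin(a) * (1 - E1) / (1 - E1 * cos(a)), tolerance = 1e-12)
  # alpha -> 0 kills the signal; TR >> T1 recovers fully
  expect_lt(spgr_two_pool_steady_state(1e-8, 0, pars, tr), 1e-7)
  expect_equal(spgr_two_pool_steady_state(deg2rad(30), 0, pars, tr = 60),
               sin(deg2rad(30)), tolerance = 1e-6)
  expect_error(spgr_two_pool_steady_state(0.1, 0.4,
                 utils::modifyList(wm_pars(), list(r1s = -2)), 8e-3), "rates")
})

test_that("DFA fit of two-pool signals reproduces the apparent-R1 model", {
  wm <- wm_pars()
  a <- deg2rad(c(3, 15))
  tr <- 8e-3
  for (beta in c(0.2, 0.42, 0.8, 1.4)) {
    s <- spgr_two_pool_steady_state(a, beta, wm, tr)
    fit <- dfa_fit(matrix(s, 1), matrix(a, 1), tr)
    expect_lt(abs(fit$r1 - apparent_r1(beta, wm)) / apparent_r1(beta, wm), 0.05)
  }
  # bias direction: fitted rate increases with B1rms
  fits <- vapply(seq(0, 1.5, by = 0.25), function(beta) {
    s <- spgr_two_pool_steady_state(a, beta, wm, tr)
    dfa_fit(matrix(s, 1), matrix(a, 1), tr)$r1
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})
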