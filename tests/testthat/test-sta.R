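test_that("excitation k-space follows the reversed-cumulative convention", {
  tm <- seq_timing()
  p0 <- kt_pulse(matrix(1 + 0i, 1, 5), timing = tm)
  expect_true(all(excitation_kspace(p0) == 0))

  tm2 <- seq_timing(n_subpulses = 2L)
  dk <- c(3, -2, 7)
  p2 <- kt_pulse(matrix(1 + 0i, 1, 2), matrix(dk, 1, 3), tm2)
  k2 <- excitation_kspace(p2)
  nsps <- tm2$samples_per_subpulse
  expect_equal(k2[1, ], -dk)
  expect_equal(k2[nsps + 1, ], c(0, 0, 0))

  blips <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 4, 3)
  p5 <- kt_pulse(matrix(1 + 0i, 1, 5), blips, tm)
  k5 <- excitation_kspace(p5)
  for (j in 1:5) {
    expected <- if (j < 5) -colSums(blips[j:4, , drop = FALSE]) else c(0, 0, 0)
    expect_equal(k5[(j - 1) * tm$samples_per_subpulse + 1, ], expected)
  }
})

test_that("subpulse k locations match brute-force integration of a triangular-blip gradient", {
  # independent oracle: sample a gradient waveform of symmetric triangular
  # blips with the prescribed moments, integrate the remaining gradient
  tm <- seq_timing()
  set.seed(5)
  blips <- matrix(runif(12, -30, 30), 4, 3)
  ndt <- 1e-7
  nb <- round(tm$blip_duration / ndt)
  tri <- function(area) {
    shape <- c(seq(0, 1, length.out = nb / 2 + 1)[-1],
               seq(1, 0, length.out = nb / 2 + 1)[-1])
    shape / sum(shape * ndt) * area / gamma_1h()   # T/m samples
  }
  nsp <- round(tm$subpulse_duration / ndt)
  gwave <- matrix(0, 0, 3)
  for (j in 1:5) {
    gwave <- rbind(gwave, matrix(0, nsp, 3))
    if (j < 5) gwave <- rbind(gwave, vapply(1:3, function(a) tri(blips[j, a]),
                                            numeric(nb)))
  }
  n_tot <- nrow(gwave)
  # k(t) = -gamma * integral_t^tau G: evaluate at each subpulse start
  kcum <- -gamma_1h() * apply(gwave[n_tot:1, ] * ndt, 2, cumsum)[n_tot:1, ]
  p <- kt_pulse(matrix(1 + 0i, 1, 5), blips, tm)
  kj <- ptxhybrid:::.subpulse_kspace(blips, 5L)
  for (j in 1:5) {
    row <- (j - 1) * (nsp + nb) + 1
    expect_equal(kj[j, ], kcum[row, ], tolerance = 1e-12)
  }
})

test_that("system matrix entries match the elementwise definition", {
  tm <- seq_timing(n_subpulses = 1L, subpulse_duration = 30e-6, dt = 10e-6)
  su <- toy_setup(matrix(1 + 0i, 2, 1), db0 = c(100, -40),
                  coords = rbind(c(0.1, 0, 0), c(-0.05, 0.02, 0)))
  k <- matrix(rep(c(10, -4, 2), each = 3), 3, 3)
  A <- system_matrix(su, tm, k, voxels = 1:2)
  # modulus is gamma*m0*dt everywhere
  expect_equal(Mod(A), matrix(gamma_1h() * 1e-5, 2, 3), tolerance = 1e-12)
  # scalar-loop oracle
  for (m in 1:2) for (n in 1:3) {
    val <- 1i * gamma_1h() * 1e-5 *
      exp(1i * 2 * pi * su$db0[m] * (tm$t[n] - tm$tau)) *
      exp(1i * sum(su$coords[m, ] * k[n, ]))
    expect_equal(A[m, n], val, tolerance = 1e-12)
  }
  # at t = tau the off-resonance phase vanishes
  tm1 <- seq_timing(n_subpulses = 1L, subpulse_duration = 10e-6, dt = 10e-6)
  expect_lt(abs(tm1$t[1] - tm1$tau), tm1$dt)  # single midpoint sample near tau
  expect_error(system_matrix(su, tm, matrix(0, 5, 3)), "n_samples")
})

test_that("flip angle map is linear in RF and matches the closed form", {
  su <- toy_setup(matrix(1 + 0i, 1, 1))
  tm <- seq_timing()   # 5 x 200 us = 1 ms RF-on
  p0 <- kt_pulse(matrix(0i, 1, 5), timing = tm)
  expect_equal(flip_angle_map(p0, su), 0)
  p1 <- kt_pulse(matrix(1 + 0i, 1, 5), timing = tm)
  a1 <- flip_angle_map(p1, su)
  expect_equal(a1, 0.26752218744, tolerance = 1e-6)   # gamma * 1uT * 1ms
  expect_equal(rad2deg(a1), 15.3, tolerance = 1e-2)
  p2 <- kt_pulse(matrix(2 + 0i, 1, 5), timing = tm)
  expect_equal(flip_angle_map(p2, su), 2 * a1, tolerance = 1e-14)
})

test_that("B1rms map follows the RMS definition and ignores blips", {
  su <- toy_setup(matrix(1 + 0i, 1, 1))
  tm <- seq_timing()
  p <- kt_pulse(matrix(1 + 0i, 1, 5), timing = tm)
  expect_equal(b1rms_map(p, su), sqrt(1 / 8), tolerance = 1e-12)
  pb <- kt_pulse(matrix(1 + 0i, 1, 5), matrix(20, 4, 3), tm)
  expect_identical(b1rms_map(pb, su), b1rms_map(p, su))
  # opposite channels cancel
  su2 <- toy_setup(matrix(c(1 + 0i, -1 + 0i), 1, 2))
  p2 <- kt_pulse(matrix(1 + 0i, 2, 5), timing = tm)
  expect_equal(b1rms_map(p2, su2), 0)
  # oracle: explicit waveform expansion of a random 8-channel pulse
  set.seed(9)
  su8 <- toy_setup(matrix(complex(real = rnorm(8), imaginary = rnorm(8)), 1, 8))
  rf <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 8, 5) * 30
  p8 <- kt_pulse(rf, matrix(runif(12, -20, 20), 4, 3), tm)
  b1_t <- as.vector(su8$sens %*% rf)[tm$subpulse_of]    # per-sample field
  beta_oracle <- sqrt(sum(Mod(b1_t)^2 * tm$dt) / tm$tr)
  expect_equal(b1rms_map(p8, su8), beta_oracle, tolerance = 1e-12)
})

test_that("pulse shape factors integrate the normalized envelope", {
  expect_equal(unclass(pulse_shape_factors(rep(1, 10)))[c("p1", "p2")],
               list(p1 = 1, p2 = 1))
  sh <- kt_shape_factors(seq_timing())
  expect_equal(sh$p1, 5 / 7, tolerance = 1e-12)
  expect_equal(sh$p2, 5 / 7, tolerance = 1e-12)
  half <- pulse_shape_factors(c(1, rep(0.5, 9)))   # mostly half-amplitude
  expect_true(half$p2 <= 1 && abs(half$p1) <= sqrt(half$p2))
  expect_error(pulse_shape_factors(numeric(0)), "empty")
  expect_error(pulse_shape_factors(rep(0.5, 4)), "unit amplitude")
})

test_that("beta_min matches the analytic bound and scales linearly", {
  tm <- seq_timing()
  sh <- kt_shape_factors(tm)
  bm15 <- beta_min(deg2rad(15), sh, tm)
  expect_equal(bm15, 0.3460, tolerance = 1e-4)
  expect_equal(beta_min(deg2rad(3), sh, tm), bm15 / 5, tolerance = 1e-12)
  expect_equal(beta_min(0, sh, tm), 0)
  expect_error(beta_min(deg2rad(15), list(p1 = 0, p2 = 0.5), tm), "p1")
})

test_that("beta_min is invariant to zero-padding the waveform", {
  tm <- seq_timing()
  bm <- beta_min(deg2rad(15), kt_shape_factors(tm), tm)
  # longer blip gaps change tau, p1, p2 consistently
  for (gap in c(200e-6, 500e-6)) {
    tmg <- seq_timing(blip_duration = gap)
    expect_equal(beta_min(deg2rad(15), kt_shape_factors(tmg), tmg), bm,
                 tolerance = 1e-12)
  }
})

test_that("nrmse has the expected closed-form behavior", {
  x <- c(1, 2, 3); w <- c(1, 2, 0.5)
  expect_equal(nrmse(x, x, w), 0)
  expect_equal(nrmse(0 * x, 2, w), 1)
  expect_equal(nrmse(rep(2 * 1.05, 3), 2, w), 0.05, tolerance = 1e-12)
  expect_error(nrmse(x, 0, w), "zero")
})

test_that("on-resonance rectangular trains satisfy the flip/B1rms equality", {
  # single channel, no off-resonance, no blips: Bloch flip angle equals
  # gamma * p1 * sqrt(TR*tau/p2) * beta to better than 0.1% at 15 degrees
  tm <- seq_timing()
  sh <- kt_shape_factors(tm)
  su <- toy_setup(matrix(1 + 0i, 1, 1))
  amp <- 0.2617994 / (gamma_1h() * 1e-6 * 1e-3)   # ~15 degrees over 1 ms on
  p <- kt_pulse(matrix(amp + 0i, 1, 5), timing = tm)
  ab <- bloch_simulate(p, su)
  bound <- gamma_1h() * sh$p1 * sqrt(tm$tr * tm$tau / sh$p2) *
    b1rms_map(p, su) * 1e-6
  expect_lt(abs(ab - bound) / bound, 1e-3)
})

test_that("the B1rms bound on flip angle holds for random off-resonant blipped pulses", {
  tm <- seq_timing()
  sh <- kt_shape_factors(tm)
  fac <- gamma_1h() * sh$p1 * sqrt(tm$tr * tm$tau / sh$p2) * 1e-6
  set.seed(77)
  n_vox <- 5L
  for (i in 1:200) {
    su <- toy_setup(matrix(complex(real = rnorm(2 * n_vox), imaginary = rnorm(2 * n_vox)),
                           n_vox, 2) * 0.003,
                    db0 = runif(n_vox, -300, 300),
                    coords = matrix(runif(3 * n_vox, -0.1, 0.1), n_vox, 3))
    p <- kt_pulse(matrix(complex(real = rnorm(10), imaginary = rnorm(10)), 2, 5) * 50,
                  matrix(runif(12, -50, 50), 4, 3), tm)
    ab <- bloch_simulate(p, su)
    expect_true(all(ab <= fac * b1rms_map(p, su) + 1e-9))
  }
})
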