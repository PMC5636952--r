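cm1 <- nnpir_constants$cm1_per_invfs

test_that("dipole derivative is exact for constant and linear signals", {
  dt <- 0.5
  t <- (0:99) * dt
  expect_equal(dipole_derivative(cbind(1, 2, 3)[rep(1, 100), ], dt),
               matrix(0, 98, 3))
  lin <- cbind(0, 0, 3 * t)
  expect_equal(dipole_derivative(lin, dt)[, 3], rep(3, 98))
  # cosine: matches the analytic derivative to O(dt^2) (sinc factor)
  nu <- 0.02
  mu <- cbind(0, 0, cos(2 * pi * nu * t))
  d <- dipole_derivative(mu, dt)[, 3]
  analytic <- -2 * pi * nu * sin(2 * pi * nu * t[2:99])
  sinc <- sin(2 * pi * nu * dt) / (2 * pi * nu * dt)
  expect_lt(max(abs(d - analytic * sinc)), 1e-12)
  expect_error(dipole_derivative(mu[1:2, ], dt), "3 frames")
})

test_that("autocorrelation matches its definition and closed forms", {
  set.seed(21)
  x <- matrix(rnorm(1500), 500, 3)
  C <- autocorrelation(x, 40)
  expect_equal(C[1], mean(rowSums(x^2)))
  # direct-loop oracle at a few lags
  for (lag in c(1, 7, 40)) {
    n <- nrow(x)
    oracle <- mean(rowSums(x[1:(n - lag), ] * x[(1 + lag):n, ]))
    expect_equal(C[lag + 1], oracle, tolerance = 1e-10)
  }
  # white noise: decorrelated beyond lag zero
  expect_lt(max(abs(C[-1])), 4 / sqrt(400))
  # pure cosine: C(tau) proportional to cos(2 pi nu tau)
  t <- 0:999
  cosx <- cbind(cos(2 * pi * 0.05 * t), 0, 0)
  Cc <- autocorrelation(cosx, 100)
  expect_lt(max(abs(Cc / Cc[1] - cos(2 * pi * 0.05 * (0:100)))), 0.05)
})

test_that("a pure cosine dipole yields a single peak at its frequency", {
  dt <- 0.5
  n <- 20001  # 10 ps
  nu <- 1000 / cm1
  mu <- cbind(0, 0, cos(2 * pi * nu * (0:(n - 1)) * dt))
  sp <- ir_spectrum(list(dipoles = mu, dt = dt))
  expect_lt(abs(spectrum_peak(sp) - 1000), 1 / (n * dt) * cm1)
  # constant dipole: flat zero spectrum
  flat <- ir_spectrum(list(dipoles = matrix(1, 5000, 3), dt = dt))
  expect_equal(max(flat$intensity), 0)
  expect_true(all(diff(sp$wavenumber) > 0))
  expect_error(ir_spectrum(list(dipoles = NULL, dt = dt)), "dipole")
})

test_that("two separated cosines keep the squared-amplitude intensity ratio", {
  dt <- 0.5
  n <- 40001
  t <- (0:(n - 1)) * dt
  nu1 <- 1000 / cm1; nu2 <- 2200 / cm1
  a1 <- 1.0; a2 <- 0.5
  mu <- cbind(0, 0, a1 * cos(2 * pi * nu1 * t) + a2 * cos(2 * pi * nu2 * t))
  sp <- ir_spectrum(list(dipoles = mu, dt = dt))
  i1 <- max(sp$intensity[abs(sp$wavenumber - 1000) < 60])
  i2 <- max(sp$intensity[abs(sp$wavenumber - 2200) < 60])
  # the derivative scales each line by its angular frequency
  expect_lt(abs(i2 / i1 - (a2 * nu2 / (a1 * nu1))^2) /
              (a2 * nu2 / (a1 * nu1))^2, 0.05)
})

test_that("zero padding interpolates without changing integrated intensity", {
  dt <- 0.5
  n <- 8001
  nu <- 1500 / cm1
  mu <- cbind(0, 0, cos(2 * pi * nu * (0:(n - 1)) * dt))
  s2 <- ir_spectrum(list(dipoles = mu, dt = dt),
                    spectrum_config(zero_padding = 2, normalize = FALSE))
  s4 <- ir_spectrum(list(dipoles = mu, dt = dt),
                    spectrum_config(zero_padding = 4, normalize = FALSE))
  # Parseval: the integrated spectral power is fixed by the (identical)
  # time-domain signal, whatever the padding; the grid only interpolates
  int2 <- sum(s2$intensity^2) * s2$resolution
  int4 <- sum(s4$intensity^2) * s4$resolution
  expect_lt(abs(int2 - int4) / int2, 1e-6)
  # and the peak location is refined, not moved
  expect_lt(abs(spectrum_peak(s2) - spectrum_peak(s4)), 2 * s2$resolution)
})

test_that("the spectrum is invariant under rigid rotation of the trajectory", {
  dt <- 0.5
  t <- (0:8000) * dt
  mu <- cbind(0.3 * cos(2 * pi * 1200 / cm1 * t),
              0.2 * sin(2 * pi * 1200 / cm1 * t), 0)
  R <- nnpir:::rotation_matrix(c(1, 1, 0), 1.2)
  sp1 <- ir_spectrum(list(dipoles = mu, dt = dt))
  sp2 <- ir_spectrum(list(dipoles = mu %*% t(R), dt = dt))
  expect_equal(sp1$intensity, sp2$intensity, tolerance = 1e-8)
})

test_that("harmonic analysis recovers closed-form frequencies and symmetry", {
  k <- 1000; r0 <- 1.1
  sys <- surrogate_system("harmonic_diatomic", k = k, r0 = r0)
  ha <- harmonic_analysis(sys$calculator, sys$config,
                          dipole_calc = sys$calculator)
  m <- atomic_masses(sys$config$elements)
  mr <- prod(m) / sum(m)
  omega <- sqrt(k / nnpir_constants$kcal_per_internal / mr)
  exact <- omega / (2 * pi) * cm1
  stretch <- max(ha$frequencies)
  expect_lt(abs(stretch - exact) / exact, 1e-3)
  # five near-zero modes (3 translations + 2 rotations of a linear molecule)
  expect_lt(sort(abs(ha$frequencies))[5], 5)
  # translations of a neutral molecule are IR-dark; the stretch is bright
  # (rotations of a polar diatomic reorient mu, so they are not compared)
  m3 <- rep(sqrt(m), each = 3)
  trans_overlap <- vapply(seq_len(6), function(k) {
    max(vapply(1:3, function(d) {
      tvec <- rep(0, 6); tvec[c(d, d + 3)] <- m3[c(d, d + 3)]
      abs(sum(ha$modes[, k] * tvec / sqrt(sum(tvec^2))))
    }, 0))
  }, 0)
  trans_modes <- order(trans_overlap, decreasing = TRUE)[1:3]
  stretch_i <- ha$intensities[which.max(ha$frequencies)]
  expect_gt(stretch_i, 0)
  expect_gt(stretch_i, 100 * max(ha$intensities[trans_modes]))
})

test_that("MD peak of a near-harmonic system matches the static analysis", {
  sys <- surrogate_system("harmonic_diatomic")
  ha <- harmonic_analysis(sys$calculator, sys$config)
  mc <- md_config(timestep = 0.4, temperature = 150, thermostat = "langevin",
                  friction = 0.002, n_steps = 12000,
                  equilibration_steps = 500, seed = 17)
  traj <- run_md(sys$calculator, sys$config, mc, dipole_calc = sys$calculator)
  pk <- spectrum_peak(ir_spectrum(traj), c(300, 4000))
  expect_lt(abs(pk - max(ha$frequencies)) / max(ha$frequencies), 0.02)
})

test_that("charge-velocity and finite-difference derivatives agree on peaks", {
  sys <- surrogate_system("morse_diatomic")
  mc <- md_config(timestep = 0.5, temperature = 300, thermostat = "langevin",
                  friction = 0.005, n_steps = 8000,
                  equilibration_steps = 500, seed = 23)
  traj <- run_md(sys$calculator, sys$config, mc, dipole_calc = sys$calculator)
  pk_cd <- spectrum_peak(ir_spectrum(traj), c(500, 3000))
  pk_cv <- spectrum_peak(
    ir_spectrum(traj, spectrum_config(derivative = "charge_velocity")),
    c(500, 3000))
  expect_lt(abs(pk_cd - pk_cv) / pk_cd, 0.02)
})
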