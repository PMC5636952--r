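test_that("energy+force cost reduces to its closed forms", {
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  m <- hdnnp(p, hidden = c(4, 4), seed = 2)
  sys <- surrogate_system("morse_diatomic")
  ds <- generate_dataset(sys$calculator, sys$config, 4, temperature = 300,
                         seed = 5)
  # labels produced by the model itself give zero cost
  self <- lapply(ds, function(d) {
    pred <- hdnnp_predict(m, d, forces = TRUE)
    d$energy <- pred$energy; d$forces <- pred$forces; d
  })
  expect_lt(energy_force_cost(m, self, eta = 1), 1e-20)
  # eta = 0 is exactly the mean squared energy error
  mse <- mean(vapply(ds, function(d)
    (hdnnp_predict(m, d)$energy - d$energy)^2, 0))
  expect_equal(energy_force_cost(m, ds, eta = 0), mse)
  # two-record toy against a loop-accumulated oracle
  two <- ds[1:2]
  oracle <- 0
  for (d in two) {
    pred <- hdnnp_predict(m, d, forces = TRUE)
    oracle <- oracle + (pred$energy - d$energy)^2 +
      2.5 * sum((pred$forces - d$forces)^2) / (3 * n_atoms(d))
  }
  expect_equal(energy_force_cost(m, two, eta = 2.5), oracle / 2)
  # records without forces fall back to the energy term with a warning
  noF <- lapply(ds, function(d) { d$forces <- NULL; d })
  expect_warning(c0 <- energy_force_cost(m, noF, eta = 1), "force")
  expect_equal(c0, mse)
})

test_that("zero-residual records leave the parameters unchanged", {
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  m <- hdnnp(p, hidden = c(4, 4), seed = 3)
  sys <- surrogate_system("morse_diatomic")
  d <- generate_dataset(sys$calculator, sys$config, 1, seed = 6)[[1]]
  pred <- hdnnp_predict(m, d, forces = TRUE)
  d$energy <- pred$energy; d$forces <- pred$forces
  st <- kalman_create(m, training_config())
  upd <- kalman_step(st, m, d, eta = 1)
  for (e in names(m$networks)) {
    expect_equal(nnpir:::net_get_params(upd$model$networks[[e]]),
                 nnpir:::net_get_params(m$networks[[e]]))
  }
})

test_that("Kalman training of a linear model reproduces least squares", {
  # linear single-block model: network with no hidden layer is y = w.g + b,
  # so pattern-wise Kalman = recursive least squares = normal equations
  set.seed(8)
  p <- descriptor_params("C", cutoff = 4)
  m <- hdnnp(p, hidden = integer(0), seed = 4)
  ds <- lapply(1:25, function(i) {
    cfg <- random_molecule(3, "C", box = 3)
    cfg$energy <- 0  # placeholder, set below
    cfg
  })
  feats <- lapply(ds, featurize, params = p)
  # synthetic linear ground truth in descriptor space
  w_true <- rnorm(p$length, sd = 0.3); b_true <- 0.7
  X <- t(vapply(feats, function(f)
    c(Reduce(`+`, lapply(f, `[[`, "values")), length(f)), numeric(p$length + 1)))
  y <- drop(X %*% c(w_true, b_true))
  for (i in seq_along(ds)) ds[[i]]$energy <- y[i]
  cfgk <- training_config(eta = 0, initial_covariance = 1e8,
                          noise_start = 1e-2, noise_final = 1e-2,
                          process_noise = 0)
  st <- kalman_create(m, cfgk)
  for (pass in 1:4) {
    for (i in seq_along(ds)) {
      upd <- kalman_step(st, m, ds[[i]], eta = 0, features = feats[[i]])
      st <- upd$state; m <- upd$model
    }
  }
  beta_ls <- qr.coef(qr(X), y)
  beta_ls[is.na(beta_ls)] <- 0
  fitted_kalman <- drop(X %*% nnpir:::net_get_params(m$networks$C))
  fitted_ls <- drop(X %*% beta_ls)
  expect_lt(max(abs(fitted_kalman - fitted_ls)), 1e-6)
})

test_that("records without an element leave that element's block untouched", {
  p <- descriptor_params(c("C", "H"), cutoff = 4)
  m <- hdnnp(p, hidden = c(4, 4), seed = 5)
  cfg <- random_molecule(3, "C")
  cfg$energy <- 1.0
  st <- kalman_create(m, training_config())
  upd <- kalman_step(st, m, cfg, eta = 0)
  expect_equal(nnpir:::net_get_params(upd$model$networks$H),
               nnpir:::net_get_params(m$networks$H))
  expect_equal(upd$state$P$H, st$P$H)
  expect_false(isTRUE(all.equal(nnpir:::net_get_params(upd$model$networks$C),
                                nnpir:::net_get_params(m$networks$C))))
})

test_that("refitting data generated by the model itself keeps cost near zero", {
  set.seed(31)
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  m <- hdnnp(p, hidden = c(5, 5), seed = 6)
  sys <- surrogate_system("morse_diatomic")
  geo <- generate_dataset(sys$calculator, sys$config, 12, seed = 7)
  self <- lapply(geo, function(d) {
    pred <- hdnnp_predict(m, d, forces = TRUE)
    d$energy <- pred$energy; d$forces <- pred$forces; d
  })
  fit <- train_hdnnp(m, self, training_config(epochs = 2, eta = 1,
                                              validation_fraction = 0,
                                              seed = 3),
                     refit_scaling = FALSE)
  expect_lt(energy_force_cost(fit$model, self, eta = 1), 1e-10)
})

test_that("force training with eta > 0 does not hurt held-out forces", {
  sys <- surrogate_system("morse_diatomic")
  ds <- generate_dataset(sys$calculator, sys$config, 60, temperature = 500,
                         seed = 41)
  hold <- generate_dataset(sys$calculator, sys$config, 20, temperature = 500,
                           seed = 42)
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  fmae <- vapply(c(0, 1), function(eta) {
    fit <- train_hdnnp(hdnnp(p, hidden = c(8, 8), seed = 5), ds,
                       training_config(eta = eta, epochs = 8,
                                       validation_fraction = 0.15, seed = 7))
    mean(vapply(hold, function(d)
      mean(abs(hdnnp_forces(fit$model, d) - d$forces)), 0))
  }, 0)
  expect_lte(fmae[2], fmae[1])
})

test_that("training history is deterministic for a fixed seed", {
  sys <- surrogate_system("morse_diatomic")
  ds <- generate_dataset(sys$calculator, sys$config, 20, seed = 51)
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  run <- function() {
    train_hdnnp(hdnnp(p, hidden = c(5, 5), seed = 2), ds,
                training_config(epochs = 3, validation_fraction = 0.2,
                                seed = 11))$history
  }
  expect_equal(run(), run())
})
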