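make_seeded_ensemble <- function(J = 2, hidden = c(5, 5), seed = 30) {
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  new_ensemble(p, J = J, hidden = hidden, seed = seed)
}

test_that("an infinite threshold adds nothing and terminates converged", {
  sys <- surrogate_system("morse_diatomic")
  seed_ds <- generate_dataset(sys$calculator, sys$config, 5, seed = 1)
  cfg <- sampling_config(uncertainty_threshold = Inf, temperature = 300,
                         run_steps = 50, max_reference_calls = 5,
                         train_config = training_config(eta = 0, epochs = 2,
                                                        validation_fraction = 0,
                                                        seed = 2),
                         seed = 3)
  res <- adaptive_sample(make_seeded_ensemble(), sys$calculator, seed_ds, cfg)
  expect_length(res$dataset, 5L)
  expect_equal(res$termination, "converged")
})

test_that("the reference-call budget is honored and growth is monotone", {
  sys <- surrogate_system("morse_diatomic")
  seed_ds <- generate_dataset(sys$calculator, sys$config, 3, seed = 4)
  cfg <- sampling_config(uncertainty_threshold = 1e-6, temperature = 500,
                         run_steps = 100, max_reference_calls = 4,
                         train_config = training_config(eta = 0, epochs = 1,
                                                        validation_fraction = 0,
                                                        seed = 5),
                         seed = 6)
  res <- adaptive_sample(make_seeded_ensemble(), sys$calculator, seed_ds, cfg)
  expect_lte(sum(res$log$action %in% c("added", "duplicate-skipped")), 4L)
  expect_true(all(diff(res$log$dataset_size) >= 0))
  # every added point was above threshold when selected
  added <- res$log[res$log$action == "added", ]
  expect_true(all(added$uncertainty > 1e-6))
  # every added configuration carries reference labels
  for (d in res$dataset) {
    expect_false(is.null(d$energy))
    expect_false(is.null(d$forces))
  }
})

test_that("reference failures are quarantined, not fatal", {
  sys <- surrogate_system("morse_diatomic")
  seed_ds <- generate_dataset(sys$calculator, sys$config, 3, seed = 7)
  flaky <- function_calculator(function(cfg) stop("reference exploded"))
  cfg <- sampling_config(uncertainty_threshold = 1e-9, temperature = 500,
                         run_steps = 30, max_reference_calls = 2,
                         train_config = training_config(eta = 0, epochs = 1,
                                                        validation_fraction = 0,
                                                        seed = 8),
                         seed = 9)
  # budget counts only successful calls; cap iterations via run length
  res <- tryCatch(
    adaptive_sample(make_seeded_ensemble(), flaky, seed_ds, cfg),
    error = function(e) e)
  expect_false(inherits(res, "error"))
  expect_true(any(res$log$action == "reference-failed-quarantined"))
  expect_length(res$dataset, 3L)
})

test_that("upscaling with the identical calculator leaves labels unchanged", {
  sys <- surrogate_system("morse_diatomic")
  ds <- generate_dataset(sys$calculator, sys$config, 6, seed = 10)
  up <- upscale(ds, sys$calculator)
  for (i in seq_along(ds)) {
    expect_equal(up[[i]]$energy, ds[[i]]$energy)
    expect_equal(up[[i]]$forces, ds[[i]]$forces)
    expect_identical(up[[i]]$positions, ds[[i]]$positions)
  }
  expect_length(attr(up, "failures"), 0L)
})

test_that("upscaling to a shifted surrogate changes labels by the known profile", {
  lo <- surrogate_system("morse_diatomic", De = 150)
  hi <- surrogate_system("morse_diatomic", De = 180)
  ds <- generate_dataset(lo$calculator, lo$config, 8, seed = 11)
  up <- upscale(ds, hi$calculator, level_name = "deep")
  for (i in seq_along(ds)) {
    r <- sqrt(sum((ds[[i]]$positions[2, ] - ds[[i]]$positions[1, ])^2))
    shift <- (180 - 150) * ((1 - exp(-2 * (r - 1.13)))^2 - 1)
    expect_equal(up[[i]]$energy - ds[[i]]$energy, shift, tolerance = 1e-9)
    expect_equal(attr(up[[i]], "provenance")[[1]]$level, "deep")
  }
  # per-configuration failures are collected, not fatal
  bad <- function_calculator(function(cfg) stop("no convergence"))
  up2 <- upscale(ds, bad)
  expect_length(attr(up2, "failures"), 8L)
  expect_equal(up2[[1]]$energy, ds[[1]]$energy)
})

test_that("retraining after upscaling tracks the new reference surface", {
  lo <- surrogate_system("morse_diatomic", De = 150)
  hi <- surrogate_system("morse_diatomic", De = 180)
  ds <- generate_dataset(lo$calculator, lo$config, 40, temperature = 500,
                         seed = 12)
  p <- descriptor_params(c("C", "O"), cutoff = 4, angular_eta = numeric(0))
  tc <- training_config(eta = 1, epochs = 6, validation_fraction = 0.1,
                        seed = 13)
  fit_lo <- train_hdnnp(hdnnp(p, hidden = c(6, 6), seed = 3), ds, tc)
  fit_hi <- train_hdnnp(hdnnp(p, hidden = c(6, 6), seed = 3),
                        upscale(ds, hi$calculator), tc)
  hold <- generate_dataset(hi$calculator, hi$config, 15, temperature = 500,
                           seed = 14)
  err_hi <- mean(vapply(hold, function(d)
    abs(total_energy(fit_hi$model, d) - d$energy), 0))
  err_lo <- mean(vapply(hold, function(d)
    abs(total_energy(fit_lo$model, d) - d$energy), 0))
  expect_lt(err_hi, err_lo)
  expect_lt(err_hi, 0.5)
})

test_that("a dense seed set needs few additions", {
  sys <- surrogate_system("morse_diatomic")
  dense <- generate_dataset(sys$calculator, sys$config, 60, temperature = 500,
                            seed = 15)
  cfg <- sampling_config(uncertainty_threshold = 0.15, temperature = 400,
                         run_steps = 200, max_reference_calls = 10,
                         train_config = training_config(eta = 1, epochs = 5,
                                                        validation_fraction = 0,
                                                        seed = 16),
                         seed = 17)
  res <- adaptive_sample(make_seeded_ensemble(J = 2, hidden = c(8, 8)),
                         sys$calculator, dense, cfg)
  expect_lte(length(res$dataset) - 60, 3)  # <= 5% of the seed size
})
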