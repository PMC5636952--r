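test_that("cosine cutoff has the required boundary values and smoothness", {
  expect_equal(cutoff_function(0, 6), 1)
  expect_equal(cutoff_function(6, 6), 0)
  expect_equal(cutoff_function(3, 6), 0.5)
  expect_equal(cutoff_function(7, 6), 0)
  # value and first derivative continuous at the cutoff
  eps <- 1e-7
  expect_lt(cutoff_function(6 - eps, 6), 1e-12)
  d <- (cutoff_function(6 - eps, 6) - cutoff_function(6 - 2 * eps, 6)) / eps
  expect_lt(abs(d), 1e-6)
  expect_error(cutoff_function(-1, 6), "non-negative")
  expect_error(cutoff_function(1, 0), "positive")
})

test_that("radial function reduces to its closed forms", {
  two <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  lone <- atomic_config("C", matrix(0, 1, 3))
  expect_equal(radial_function(lone, 1, 0.3, 0, 6, "C"), 0)
  # eta = 0: reduces to fc(3.0) = 0.5
  expect_equal(radial_function(two, 1, 0, 0, 6, "C"), 0.5)
  two2 <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radial_function(two2, 1, 1, 0, 6, "C"),
               exp(-4) * cutoff_function(2, 6))
})

test_that("angular function matches the brute-force oracle and edge cases", {
  two <- atomic_config(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(angular_function(two, 1, 0.01, 2, 1, 6, c("H", "H")), 0)
  # linear triple with lambda = +1, zeta = 1 vanishes: (1 + cos 180) = 0
  lin <- atomic_config(c("C", "H", "H"),
                       rbind(c(0, 0, 0), c(1.1, 0, 0), c(-1.1, 0, 0)))
  expect_equal(angular_function(lin, 1, 0, 1, 1, 6, c("H", "H")), 0)
  # water-like oracle evaluated from the formula directly
  w <- surrogate_system("water_like")$config
  rij <- sqrt(sum((w$positions[2, ] - w$positions[1, ])^2))
  rik <- sqrt(sum((w$positions[3, ] - w$positions[1, ])^2))
  rjk <- sqrt(sum((w$positions[3, ] - w$positions[2, ])^2))
  cost <- sum((w$positions[2, ] - w$positions[1, ]) *
              (w$positions[3, ] - w$positions[1, ])) / (rij * rik)
  manual <- 2^(1 - 4) * (1 + (-1) * cost)^4 *
    exp(-0.01 * (rij^2 + rik^2 + rjk^2)) *
    cutoff_function(rij, 4) * cutoff_function(rik, 4) *
    cutoff_function(rjk, 4)
  expect_equal(angular_function(w, 1, 0.01, 4, -1, 4, c("H", "H")), manual)
})

test_that("featurize agrees with the scalar reference functions", {
  set.seed(4)
  cfg <- random_molecule(5, c("C", "H"))
  p <- descriptor_params(c("C", "H"), cutoff = 4)
  f <- featurize(cfg, p)
  # radial block: element order sorted C, H; 5 eta values each
  for (i in c(1, 3)) {
    for (e in seq_along(p$elements)) {
      for (r in seq_len(nrow(p$radial))) {
        expect_equal(f[[i]]$values[(e - 1) * 5 + r],
                     radial_function(cfg, i, p$radial$eta[r], p$radial$rs[r],
                                     4, p$elements[e]))
      }
    }
  }
  # one angular component per pair, spot-checked
  for (pi_ in seq_along(p$element_pairs)) {
    ang <- p$angular
    expect_equal(f[[2]]$values[10 + (pi_ - 1) * nrow(ang) + 3],
                 angular_function(cfg, 2, ang$eta[3], ang$zeta[3],
                                  ang$lambda[3], 4, p$element_pairs[[pi_]]))
  }
})

test_that("descriptors are invariant under rigid motion and permutation", {
  set.seed(7)
  cfg <- random_molecule(6, c("C", "H", "O"))
  p <- descriptor_params(c("C", "H", "O"), cutoff = 4)
  f0 <- featurize(cfg, p)
  R <- nnpir:::rotation_matrix(c(1, 2, 0.5), 1.1)
  f1 <- featurize(transform_config(cfg, R, c(3, -2, 0.7)), p)
  for (i in seq_along(f0)) {
    expect_lt(max(abs(f0[[i]]$values - f1[[i]]$values)), 1e-10)
  }
  # swap two same-element atoms: multiset of vectors unchanged
  same <- which(cfg$elements == cfg$elements[which.max(table(cfg$elements) > 1)])
  idx <- which(cfg$elements == names(sort(table(cfg$elements),
                                          decreasing = TRUE))[1])[1:2]
  cfg2 <- cfg
  cfg2$positions[idx, ] <- cfg$positions[rev(idx), ]
  f2 <- featurize(cfg2, p)
  m0 <- do.call(rbind, lapply(f0, `[[`, "values"))
  m2 <- do.call(rbind, lapply(f2, `[[`, "values"))
  expect_lt(max(abs(m0[-idx, ] - m2[-idx, ])), 1e-10)
  expect_lt(max(abs(m0[idx, ] - m2[rev(idx), ])), 1e-10)
})

test_that("descriptor jacobians match central finite differences", {
  set.seed(11)
  for (rep in 1:3) {
    cfg <- random_molecule(4, c("C", "H"))
    p <- descriptor_params(c("C", "H"), cutoff = 4)
    f <- featurize(cfg, p, jacobian = TRUE)
    h <- 1e-4
    for (i in seq_len(4)) {
      for (at in seq_len(4)) {
        for (d in 1:3) {
          cp <- cfg; cp$positions[at, d] <- cp$positions[at, d] + h
          cm <- cfg; cm$positions[at, d] <- cm$positions[at, d] - h
          fd <- (featurize(cp, p)[[i]]$values -
                 featurize(cm, p)[[i]]$values) / (2 * h)
          an <- f[[i]]$jacobian[, 3 * (at - 1) + d]
          scale <- pmax(abs(fd), 1)
          expect_lt(max(abs(fd - an) / scale), 1e-6)
        }
      }
    }
  }
})

test_that("descriptors vanish smoothly as neighbors leave the cutoff", {
  p <- descriptor_params("C", cutoff = 4)
  vals <- vapply(c(3.5, 3.9, 3.999, 4.1), function(r) {
    cfg <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(r, 0, 0)))
    sum(abs(featurize(cfg, p)[[1]]$values))
  }, 0)
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[4], 0)
  expect_lt(vals[3], 1e-5)
})

test_that("featurize rejects degenerate and uncovered inputs", {
  p <- descriptor_params("C", cutoff = 4)
  bad <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(featurize(bad, p), "degenerate")
  other <- atomic_config("N", matrix(0, 1, 3))
  expect_error(featurize(other, p), "N")
})
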