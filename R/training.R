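# Combined energy + force training of HDNNPs with an element-decoupled
# extended Kalman filter: each element's network parameters carry their own
# covariance matrix and are updated from the jacobian of the predicted energy
# (and each Cartesian force component, scaled by sqrt(eta)) with respect to
# that element's parameters only; cross-element covariance is dropped. In the
# linear single-block case this reduces exactly to recursive least squares.

#' Training settings
#'
#' @param eta Force weight in the cost (dimensionless, >= 0; default 1).
#'   Folds every Cartesian force component into the filter as an extra scalar
#'   measurement weighted by sqrt(eta).
#' @param epochs Number of passes over the training set (>= 1).
#' @param process_noise Kalman process noise added to the covariance diagonal
#'   each update (default 1e-6).
#' @param initial_covariance Scale of the initial parameter covariance
#'   (default 1; larger values make the first updates more aggressive and can
#'   saturate the hidden units).
#' @param noise_start,noise_final,noise_decay Measurement-noise annealing
#'   schedule: r_epoch = max(noise_final, noise_start * noise_decay^epoch),
#'   in units of the squared target scale (the filter weights every
#'   measurement by the training-set energy-residual/force-component
#'   standard deviations).
#' @param validation_fraction Fraction of records held out for validation
#'   (0 <= f < 1).
#' @param patience Early-stop patience in epochs (Inf disables).
#' @param seed Integer seed (shuffling and the validation split).
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(eta = 1, epochs = 20, process_noise = 1e-6,
                            initial_covariance = 1,
                            noise_start = 1, noise_final = 1e-4,
                            noise_decay = 0.5,
                            validation_fraction = 0.1, patience = Inf,
                            seed = 1L) {
  if (eta < 0) stop("eta must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation fraction must be in [0, 1)")
  }
  structure(list(eta = eta, epochs = as.integer(epochs),
                 process_noise = process_noise,
                 initial_covariance = initial_covariance,
                 noise_start = noise_start, noise_final = noise_final,
                 noise_decay = noise_decay,
                 validation_fraction = validation_fraction,
                 patience = patience, seed = as.integer(seed)),
            class = "training_config")
}

#' Energy + force cost
#'
#' (1/M) sum_m (E_hat_m - E_m)^2 +
#' (eta/M) sum_m (1/(3 N_m)) sum_alpha (F_hat_alpha - F_alpha)^2.
#' Records lacking forces contribute only the energy term (with a one-time
#' warning).
#'
#' @param model An \code{hdnnp}.
#' @param dataset List of labeled \code{atomic_config}s.
#' @param eta Force weight.
#' @return Cost in (kcal/mol)^2.
#' @export
energy_force_cost <- function(model, dataset, eta = 1) {
  if (!length(dataset)) stop("empty dataset")
  warned <- FALSE
  total <- 0
  for (d in dataset) {
    pred <- hdnnp_predict(model, d, forces = eta > 0 && !is.null(d$forces))
    total <- total + (pred$energy - d$energy)^2
    if (eta > 0) {
      if (is.null(d$forces)) {
        if (!warned) {
          warning("record(s) without forces: force term skipped")
          warned <- TRUE
        }
      } else {
        total <- total + eta * sum((pred$forces - d$forces)^2) /
          (3 * n_atoms(d))
      }
    }
  }
  total / length(dataset)
}

#' Initialize the Kalman state for a model
#'
#' One covariance block per element, \code{initial_covariance * I}.
#'
#' @param model An \code{hdnnp} or \code{dipole_model}.
#' @param config A \code{training_config}.
#' @return An object of class \code{kalman_state}.
#' @export
kalman_create <- function(model, config = training_config()) {
  P <- lapply(model$networks, function(net)
    diag(config$initial_covariance, n_params(net)))
  structure(list(P = P, step = 0L, noise = config$noise_start,
                 process_noise = config$process_noise,
                 sigma_e = 1, sigma_f = 1,
                 reconditioned = 0L),
            class = "kalman_state")
}

# Per-element prediction jacobians for one featurized record.
# Returns energy, forces (if requested), and per element: dE/dtheta (p) and
# d(vec F)/dtheta (p x 3N).
.record_jacobians <- function(model, features, with_forces = TRUE) {
  n <- length(features)
  els <- names(model$networks)
  energy <- 0
  Fvec <- numeric(3L * n)
  He <- stats::setNames(vector("list", length(els)), els)
  Hf <- stats::setNames(vector("list", length(els)), els)
  for (e in els) {
    He[[e]] <- numeric(n_params(model$networks[[e]]))
    if (with_forces) Hf[[e]] <- matrix(0, n_params(model$networks[[e]]), 3L * n)
  }
  for (i in seq_len(n)) {
    f <- features[[i]]
    e <- f$element
    net <- model$networks[[e]]
    s <- model$scaling[[e]]
    x <- (f$values - s$center) / s$scale
    gr <- net_gradients(net, x, params = TRUE, input = with_forces)
    energy <- energy + gr$y + model$energy_shifts[[e]]
    He[[e]] <- He[[e]] + gr$pgrad
    if (with_forces) {
      gx <- gr$xgrad / s$scale
      Fvec <- Fvec - drop(crossprod(f$jacobian, gx))
      M <- net_mixed_jacobian(net, x)
      M <- M * rep(1 / s$scale, each = nrow(M))
      Hf[[e]] <- Hf[[e]] - M %*% f$jacobian
    }
  }
  list(energy = energy,
       forces = if (with_forces) matrix(Fvec, n, 3, byrow = TRUE) else NULL,
       Fvec = if (with_forces) Fvec else NULL,
       He = He, Hf = Hf)
}

#' One element-decoupled Kalman update
#'
#' Processes a single labeled record: builds the innovation (reference minus
#' prediction for the energy and, when present and \code{eta > 0}, all 3N
#' force components scaled by sqrt(eta)) and applies an extended Kalman
#' update independently per element block. Elements absent from the record
#' have zero jacobian and are untouched.
#'
#' @param state A \code{kalman_state}.
#' @param model An \code{hdnnp}.
#' @param record Labeled \code{atomic_config}.
#' @param eta Force weight.
#' @param features Optional precomputed featurization (with jacobians when
#'   forces are used).
#' @return List with updated \code{state} and \code{model}.
#' @export
kalman_step <- function(state, model, record, eta = 1, features = NULL) {
  use_forces <- eta > 0 && !is.null(record$forces)
  if (is.null(features)) {
    features <- featurize(record, model$descriptor_params,
                          jacobian = use_forces)
  }
  jac <- .record_jacobians(model, features, with_forces = use_forces)
  sqeta <- sqrt(eta)
  nu <- record$energy - jac$energy
  if (use_forces) {
    ref_F <- as.vector(t(record$forces))
    nu <- c(nu, sqeta * (ref_F - jac$Fvec))
  }
  # measurement-noise variances in the natural scale of each target
  # (energy residual sd, force component sd), so innovations of very
  # different magnitudes produce comparable gains
  rvec <- state$noise * state$sigma_e^2
  if (use_forces) {
    rvec <- c(rvec, rep(state$noise * state$sigma_f^2, length(nu) - 1L))
  }
  for (e in names(model$networks)) {
    H <- if (use_forces) cbind(jac$He[[e]], sqeta * jac$Hf[[e]])
         else matrix(jac$He[[e]], ncol = 1)
    # H is p x m here; skip untouched elements (zero jacobian)
    if (max(abs(H)) == 0) next
    P <- state$P[[e]]
    PH <- P %*% H                       # p x m
    S <- crossprod(H, PH) + diag(rvec, ncol(H))
    K <- tryCatch(t(solve(S, t(PH))), error = function(err) NULL)
    if (is.null(K)) {
      # recondition: reset this block's covariance
      state$P[[e]] <- diag(mean(diag(P)), nrow(P))
      state$reconditioned <- state$reconditioned + 1L
      next
    }
    theta <- net_get_params(model$networks[[e]]) + drop(K %*% nu)
    model$networks[[e]] <- net_set_params(model$networks[[e]], theta)
    P <- P - K %*% t(PH)
    P <- (P + t(P)) / 2
    diag(P) <- diag(P) + state$process_noise
    if (any(diag(P) <= 0)) {
      state$P[[e]] <- diag(mean(abs(diag(P))) + state$process_noise, nrow(P))
      state$reconditioned <- state$reconditioned + 1L
    } else {
      state$P[[e]] <- P
    }
  }
  state$step <- state$step + 1L
  list(state = state, model = model)
}

# RMSEs of a model over featurized records.
.model_rmse <- function(model, dataset, features) {
  se_e <- 0; se_f <- 0; nf <- 0
  for (k in seq_along(dataset)) {
    d <- dataset[[k]]
    with_f <- !is.null(d$forces) && !is.null(features[[k]][[1]]$jacobian)
    pred <- hdnnp_predict(model, d, forces = with_f,
                          features = features[[k]])
    se_e <- se_e + (pred$energy - d$energy)^2
    if (with_f) {
      se_f <- se_f + sum((pred$forces - d$forces)^2)
      nf <- nf + 3 * n_atoms(d)
    }
  }
  c(energy = sqrt(se_e / length(dataset)),
    force = if (nf > 0) sqrt(se_f / nf) else NA_real_)
}

#' Train an HDNNP
#'
#' Pattern-wise element-decoupled Kalman training on energies and forces,
#' with input standardization and per-element energy shifts fitted from the
#' training split, per-epoch RMSE history, validation-based model selection
#' and early stopping. Deterministic for a fixed seed.
#'
#' @param model An \code{hdnnp} (possibly pre-trained; warm starts reuse a
#'   supplied \code{kalman} state).
#' @param dataset List of labeled \code{atomic_config}s.
#' @param config A \code{\link{training_config}}.
#' @param features Optional precomputed featurizations (one per record, with
#'   jacobians when forces are used).
#' @param kalman Optional \code{kalman_state} to continue from (warm start);
#'   when given, scaling and shifts are kept from the model.
#' @param refit_scaling If TRUE (default when no warm start) refit input
#'   scaling and energy shifts before training.
#' @return List with \code{model} (best validation checkpoint),
#'   \code{history} (per-epoch data frame), \code{kalman} (final state) and
#'   \code{diverged} flag.
#' @export
train_hdnnp <- function(model, dataset, config = training_config(),
                        features = NULL, kalman = NULL,
                        refit_scaling = is.null(kalman)) {
  if (!length(dataset)) stop("empty dataset")
  for (d in dataset) check_elements_covered(model, d)
  use_forces <- config$eta > 0 &&
    any(vapply(dataset, function(d) !is.null(d$forces), TRUE))
  if (is.null(features)) {
    features <- lapply(dataset, featurize, params = model$descriptor_params,
                       jacobian = use_forces)
  }
  old <- .Random.seed_save()
  set.seed(config$seed)
  on.exit(.Random.seed_restore(old))
  M <- length(dataset)
  n_val <- floor(config$validation_fraction * M)
  val_idx <- if (n_val > 0) sample.int(M, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(M), val_idx)
  if (refit_scaling) {
    model <- fit_scaling(model, dataset[tr_idx], features[tr_idx])
  }
  state <- if (is.null(kalman)) kalman_create(model, config) else kalman
  if (is.null(kalman)) {
    # target scales for the measurement-noise weighting
    res <- vapply(dataset[tr_idx], function(d) {
      counts <- vapply(names(model$networks),
                       function(e) sum(d$elements == e), 0)
      d$energy - sum(counts * model$energy_shifts)
    }, 0)
    state$sigma_e <- max(stats::sd(res), 1e-2)
    fcomp <- unlist(lapply(dataset[tr_idx], function(d) d$forces))
    if (length(fcomp)) state$sigma_f <- max(stats::sd(fcomp), 1e-2)
  }
  best <- list(model = model, cost = Inf, epoch = 0L)
  hist <- NULL
  diverged <- FALSE
  last_good <- model
  for (epoch in seq_len(config$epochs)) {
    state$noise <- max(config$noise_final,
                       config$noise_start * config$noise_decay^(epoch - 1))
    for (k in sample(tr_idx)) {
      upd <- kalman_step(state, model, dataset[[k]], eta = config$eta,
                         features = features[[k]])
      state <- upd$state
      theta_ok <- all(vapply(upd$model$networks,
                             function(nt) all(is.finite(net_get_params(nt))),
                             TRUE))
      if (!theta_ok) {
        diverged <- TRUE
        break
      }
      model <- upd$model
      last_good <- model
    }
    if (diverged) {
      warning("non-finite parameters during training; ",
              "returning last good checkpoint")
      model <- last_good
      break
    }
    tr_rmse <- .model_rmse(model, dataset[tr_idx], features[tr_idx])
    val_rmse <- if (length(val_idx))
      .model_rmse(model, dataset[val_idx], features[val_idx]) else tr_rmse
    sel_cost <- val_rmse["energy"]^2 +
      if (is.na(val_rmse["force"])) 0 else config$eta * val_rmse["force"]^2
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_energy_rmse = tr_rmse["energy"],
      train_force_rmse = tr_rmse["force"],
      val_energy_rmse = val_rmse["energy"],
      val_force_rmse = val_rmse["force"], row.names = NULL))
    if (sel_cost < best$cost) {
      best <- list(model = model, cost = sel_cost, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  list(model = best$model, history = hist, kalman = state,
       diverged = diverged)
}
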