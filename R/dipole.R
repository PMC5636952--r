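# Neural-network dipole model: per-element charge networks produce
# environment-dependent atomic partial charges q_i; the molecular dipole is
# mu = sum_i q_i (r_i - r_com) and the total charge Q = sum_i q_i. The
# networks are trained ONLY on molecular observables (reference dipole vector
# and total charge) -- the atomic charges are inferred indirectly and
# constitute a statistical charge-partitioning scheme.

#' Create a neural-network dipole model
#'
#' @param params A \code{\link{descriptor_params}}.
#' @param hidden Hidden layer sizes of the charge networks (default
#'   \code{c(100, 100)}, the customary ceiling for dipole models; use smaller
#'   nets for toy systems).
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{dipole_model}.
#' @export
dipole_model <- function(params, hidden = c(100, 100), seed = 1L) {
  nets <- list()
  for (i in seq_along(params$elements)) {
    e <- params$elements[i]
    nets[[e]] <- elemental_network(e, params$length, hidden,
                                   seed = seed * 2000L + i)
  }
  scaling <- lapply(nets, function(n)
    list(center = numeric(params$length), scale = rep(1, params$length)))
  structure(list(networks = nets, descriptor_params = params,
                 scaling = scaling,
                 energy_shifts = stats::setNames(rep(0, length(nets)),
                                                 names(nets)),
                 hidden = hidden, seed = seed),
            class = "dipole_model")
}

#' @export
print.dipole_model <- function(x, ...) {
  cat("<dipole_model> elements:", paste(names(x$networks), collapse = " "),
      "| architecture:", paste(c(x$descriptor_params$length, x$hidden, 1),
                               collapse = "-"), "\n")
  invisible(x)
}

#' Environment-dependent atomic charges
#'
#' @param model A \code{dipole_model}.
#' @param config An \code{atomic_config}.
#' @param features Optional precomputed featurization.
#' @return Numeric vector of charges (e), one per atom.
#' @export
atomic_charges <- function(model, config, features = NULL) {
  check_elements_covered(model, config)
  if (is.null(features)) {
    features <- featurize(config, model$descriptor_params)
  }
  vapply(features, function(f) {
    s <- model$scaling[[f$element]]
    net_forward(model$networks[[f$element]],
                (f$values - s$center) / s$scale)$y
  }, 0)
}

#' Molecular dipole from the charge model
#'
#' mu = sum_i q_i (r_i - r_com), converted from e*Angstrom to Debye. For a
#' neutral molecule (sum q = 0) the result is origin-independent.
#'
#' @inheritParams atomic_charges
#' @return List with \code{dipole} (length-3, Debye), \code{total_charge}
#'   (e) and \code{charges}.
#' @export
molecular_dipole <- function(model, config, features = NULL) {
  q <- atomic_charges(model, config, features)
  rel <- sweep(config$positions, 2, center_of_mass(config))
  list(dipole = colSums(rel * q) * nnpir_constants$debye_per_eA,
       total_charge = sum(q), charges = q)
}

#' @export
calc_evaluate.dipole_model <- function(calc, config, forces = TRUE,
                                       dipole = TRUE) {
  md <- molecular_dipole(calc, config)
  list(energy = NA_real_, dipole = md$dipole,
       total_charge = md$total_charge, charges = md$charges)
}

#' Dipole-model cost
#'
#' Mean over molecules of (Q_hat - Q)^2 + w * sum_l (mu_hat_l - mu_l)^2, the
#' charge term in e^2 and the dipole term in (e*Angstrom)^2; \code{w} is the
#' dipole/charge weight ratio (default 1).
#'
#' @param model A \code{dipole_model}.
#' @param dataset List of \code{atomic_config}s with \code{dipole} and
#'   \code{total_charge} labels.
#' @param dipole_weight Weight of the dipole term relative to the charge term.
#' @return Scalar cost.
#' @export
dipole_cost <- function(model, dataset, dipole_weight = 1) {
  if (!length(dataset)) stop("empty dataset")
  total <- 0
  for (d in dataset) {
    if (is.null(d$dipole) || is.null(d$total_charge)) {
      stop("record lacks dipole/total_charge labels")
    }
    md <- molecular_dipole(model, d)
    dmu <- (md$dipole - d$dipole) / nnpir_constants$debye_per_eA  # e*A
    total <- total + (md$total_charge - d$total_charge)^2 +
      dipole_weight * sum(dmu^2)
  }
  total / length(dataset)
}

# Jacobians of [Q, mu_x, mu_y, mu_z] (internal units e, e*A) w.r.t. each
# element's parameters, plus the predictions.
.dipole_jacobians <- function(model, config, features) {
  rel <- sweep(config$positions, 2, center_of_mass(config))
  els <- names(model$networks)
  H <- stats::setNames(lapply(els, function(e)
    matrix(0, n_params(model$networks[[e]]), 4L)), els)
  Q <- 0; mu <- c(0, 0, 0)
  for (i in seq_along(features)) {
    f <- features[[i]]
    e <- f$element
    s <- model$scaling[[e]]
    gr <- net_gradients(model$networks[[e]], (f$values - s$center) / s$scale,
                        params = TRUE, input = FALSE)
    Q <- Q + gr$y
    mu <- mu + gr$y * rel[i, ]
    H[[e]][, 1] <- H[[e]][, 1] + gr$pgrad
    H[[e]][, 2:4] <- H[[e]][, 2:4] + outer(gr$pgrad, rel[i, ])
  }
  list(Q = Q, mu = mu, H = H)
}

#' Train the dipole model
#'
#' Element-decoupled Kalman training on molecular observables only: each
#' record contributes four measurements (total charge; three dipole
#' components in e*Angstrom). An Adam-style gradient-descent fallback is
#' available via \code{optimizer = "adam"}.
#'
#' @param model A \code{dipole_model}.
#' @param dataset List of labeled \code{atomic_config}s (dipole in Debye,
#'   total charge in e).
#' @param config A \code{\link{training_config}} (\code{eta} is ignored).
#' @param optimizer "kalman" (default) or "adam".
#' @param learning_rate Adam step size.
#' @return List with \code{model}, \code{history}, \code{diverged}.
#' @export
train_dipole <- function(model, dataset, config = training_config(),
                         optimizer = c("kalman", "adam"),
                         learning_rate = 3e-3) {
  optimizer <- match.arg(optimizer)
  if (!length(dataset)) stop("empty dataset")
  for (d in dataset) {
    if (is.null(d$dipole) || is.null(d$total_charge)) {
      stop("record lacks dipole/total_charge labels")
    }
  }
  features <- lapply(dataset, featurize, params = model$descriptor_params)
  old <- .Random.seed_save()
  set.seed(config$seed)
  on.exit(.Random.seed_restore(old))
  M <- length(dataset)
  n_val <- floor(config$validation_fraction * M)
  val_idx <- if (n_val > 0) sample.int(M, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(M), val_idx)
  # input standardization from the training split
  model <- .fit_dipole_scaling(model, features[tr_idx])
  state <- kalman_create(model, config)
  adam <- if (optimizer == "adam") {
    lapply(model$networks, function(nt)
      list(m = numeric(n_params(nt)), v = numeric(n_params(nt)), t = 0))
  }
  d2e <- nnpir_constants$debye_per_eA
  best <- list(model = model, cost = Inf, epoch = 0L)
  hist <- NULL
  diverged <- FALSE
  for (epoch in seq_len(config$epochs)) {
    state$noise <- max(config$noise_final,
                       config$noise_start * config$noise_decay^(epoch - 1))
    for (k in sample(tr_idx)) {
      d <- dataset[[k]]
      jac <- .dipole_jacobians(model, d, features[[k]])
      nu <- c(d$total_charge - jac$Q, d$dipole / d2e - jac$mu)
      for (e in names(model$networks)) {
        H <- jac$H[[e]]
        if (max(abs(H)) == 0) next
        if (optimizer == "kalman") {
          P <- state$P[[e]]
          PH <- P %*% H
          S <- crossprod(H, PH) + diag(state$noise, 4L)
          K <- t(solve(S, t(PH)))
          theta <- net_get_params(model$networks[[e]]) + drop(K %*% nu)
          P <- P - K %*% t(PH)
          P <- (P + t(P)) / 2
          diag(P) <- diag(P) + state$process_noise
          state$P[[e]] <- P
        } else {
          g <- -2 * drop(H %*% nu)  # gradient of the squared error
          a <- adam[[e]]
          a$t <- a$t + 1
          a$m <- 0.9 * a$m + 0.1 * g
          a$v <- 0.999 * a$v + 0.001 * g^2
          mh <- a$m / (1 - 0.9^a$t); vh <- a$v / (1 - 0.999^a$t)
          theta <- net_get_params(model$networks[[e]]) -
            learning_rate * mh / (sqrt(vh) + 1e-8)
          adam[[e]] <- a
        }
        if (!all(is.finite(theta))) { diverged <- TRUE; break }
        model$networks[[e]] <- net_set_params(model$networks[[e]], theta)
      }
      if (diverged) break
    }
    if (diverged) {
      warning("non-finite parameters during dipole training; ",
              "returning best checkpoint")
      break
    }
    cost_tr <- dipole_cost(model, dataset[tr_idx])
    cost_val <- if (length(val_idx)) dipole_cost(model, dataset[val_idx])
                else cost_tr
    hist <- rbind(hist, data.frame(epoch = epoch, train_cost = cost_tr,
                                   val_cost = cost_val))
    if (cost_val < best$cost) {
      best <- list(model = model, cost = cost_val, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  list(model = best$model, history = hist, diverged = diverged)
}

.fit_dipole_scaling <- function(model, features) {
  for (e in names(model$networks)) {
    rows <- do.call(rbind, unlist(lapply(features, function(fr)
      lapply(Filter(function(a) a$element == e, fr), `[[`, "values")),
      recursive = FALSE))
    if (is.null(rows)) next
    ctr <- colMeans(rows)
    scl <- apply(rows, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    model$scaling[[e]] <- list(center = ctr, scale = scl)
  }
  model
}
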