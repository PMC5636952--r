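# High-dimensional neural network potential: E_pot = sum_i E_i, with E_i from
# the elemental network of atom i's element evaluated on its (standardized)
# symmetry-function vector. Forces follow analytically by the chain rule
# through the network input gradient and the descriptor jacobian.

#' Create a high-dimensional neural network potential
#'
#' One feed-forward network per element; the molecular energy is the sum of
#' per-atom network outputs plus per-element reference energies. Input
#' standardization (per descriptor component) and the per-element energy
#' shifts are fitted from data by \code{\link{fit_scaling}} (called
#' automatically by \code{\link{train_hdnnp}}).
#'
#' @param params A \code{\link{descriptor_params}}.
#' @param hidden Hidden layer sizes for every elemental network
#'   (default \code{c(35, 35)}, the customary ceiling for these potentials).
#' @param seed Integer seed; member networks of an ensemble differ by seed.
#' @return An object of class \code{hdnnp}.
#' @export
hdnnp <- function(params, hidden = c(35, 35), seed = 1L) {
  nets <- list()
  for (i in seq_along(params$elements)) {
    e <- params$elements[i]
    nets[[e]] <- elemental_network(e, params$length, hidden,
                                   seed = seed * 1000L + i)
  }
  scaling <- lapply(nets, function(n)
    list(center = numeric(params$length), scale = rep(1, params$length)))
  shifts <- stats::setNames(rep(0, length(nets)), names(nets))
  structure(list(networks = nets, descriptor_params = params,
                 scaling = scaling, energy_shifts = shifts,
                 hidden = hidden, seed = seed),
            class = "hdnnp")
}

#' @export
print.hdnnp <- function(x, ...) {
  cat("<hdnnp> elements:", paste(names(x$networks), collapse = " "),
      "| architecture:", paste(c(x$descriptor_params$length, x$hidden, 1),
                               collapse = "-"), "\n")
  invisible(x)
}

check_elements_covered <- function(model, config) {
  missing <- setdiff(unique(config$elements), names(model$networks))
  if (length(missing)) {
    stop("element(s) not covered by the model: ",
         paste(missing, collapse = ", "))
  }
}

scale_descriptor <- function(model, element, g) {
  s <- model$scaling[[element]]
  (g - s$center) / s$scale
}

#' Atomic energy contribution
#'
#' Evaluates one elemental network on a raw descriptor vector (input
#' standardization applied internally; the per-element energy shift is not
#' added, mirroring the network's own output).
#'
#' @param model An \code{hdnnp}.
#' @param element Element symbol selecting the network.
#' @param g Raw descriptor vector.
#' @return Energy contribution in kcal/mol.
#' @export
atomic_energy <- function(model, element, g) {
  net <- model$networks[[element]]
  if (is.null(net)) stop("element not covered by the model: ", element)
  if (length(g) != net$sizes[1L]) {
    stop("descriptor length ", length(g), " does not match network input ",
         net$sizes[1L])
  }
  net_forward(net, scale_descriptor(model, element, g))$y
}

#' Predict energy (and forces) with an HDNNP
#'
#' @param model An \code{hdnnp}.
#' @param config An \code{atomic_config}.
#' @param forces If TRUE also return analytic forces
#'   F = -dE/dR (kcal/mol/Angstrom).
#' @param features Optional precomputed output of \code{\link{featurize}}
#'   (with jacobians when forces are requested).
#' @return List with \code{energy} and, if requested, \code{forces}
#'   (N x 3 matrix).
#' @export
hdnnp_predict <- function(model, config, forces = FALSE, features = NULL) {
  check_elements_covered(model, config)
  if (is.null(features)) {
    features <- featurize(config, model$descriptor_params, jacobian = forces)
  }
  n <- length(features)
  energy <- 0
  F <- if (forces) numeric(3L * n) else NULL
  for (i in seq_len(n)) {
    f <- features[[i]]
    e <- f$element
    x <- scale_descriptor(model, e, f$values)
    if (forces) {
      gr <- net_gradients(model$networks[[e]], x, params = FALSE, input = TRUE)
      energy <- energy + gr$y
      # chain rule through input standardization and descriptor jacobian
      gx <- gr$xgrad / model$scaling[[e]]$scale
      F <- F + drop(crossprod(f$jacobian, gx))  # accumulate dE/dR
    } else {
      energy <- energy + net_forward(model$networks[[e]], x)$y
    }
    energy <- energy + model$energy_shifts[[e]]
  }
  out <- list(energy = energy)
  if (forces) out$forces <- matrix(-F, n, 3, byrow = TRUE)
  out
}

#' Total potential energy
#'
#' @inheritParams hdnnp_predict
#' @return Energy in kcal/mol.
#' @export
total_energy <- function(model, config, features = NULL) {
  hdnnp_predict(model, config, forces = FALSE, features = features)$energy
}

#' Analytic forces
#'
#' @inheritParams hdnnp_predict
#' @return N x 3 matrix of forces (kcal/mol/Angstrom).
#' @export
hdnnp_forces <- function(model, config, features = NULL) {
  hdnnp_predict(model, config, forces = TRUE, features = features)$forces
}

#' Fit input scaling and per-element energy shifts from a dataset
#'
#' Standardizes every descriptor component over the dataset (per element) and
#' fits per-element reference energies by least squares on element counts, so
#' the networks only model the residual interaction energy.
#'
#' @param model An \code{hdnnp}.
#' @param dataset List of labeled \code{atomic_config}s.
#' @param features Optional list of precomputed featurizations (one per
#'   record).
#' @return The model with updated \code{scaling} and \code{energy_shifts}.
#' @export
fit_scaling <- function(model, dataset, features = NULL) {
  if (is.null(features)) {
    features <- lapply(dataset, featurize, params = model$descriptor_params)
  }
  els <- names(model$networks)
  for (e in els) {
    rows <- do.call(rbind, unlist(lapply(features, function(fr)
      lapply(Filter(function(a) a$element == e, fr), `[[`, "values")),
      recursive = FALSE))
    if (is.null(rows)) next
    ctr <- colMeans(rows)
    scl <- apply(rows, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    model$scaling[[e]] <- list(center = ctr, scale = scl)
  }
  energies <- vapply(dataset, function(d) {
    if (is.null(d$energy)) stop("fit_scaling needs reference energies")
    d$energy
  }, 0)
  counts <- t(vapply(dataset, function(d)
    vapply(els, function(e) sum(d$elements == e), 0), numeric(length(els))))
  counts <- matrix(counts, nrow = length(dataset))
  fit <- tryCatch(qr.coef(qr(counts), energies), error = function(e) NULL)
  if (!is.null(fit)) {
    fit[is.na(fit)] <- 0
    model$energy_shifts[] <- fit
  }
  model
}
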