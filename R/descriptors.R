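# Atom-centered symmetry functions (ACSFs): rotation/translation/permutation
# invariant fingerprints of each atom's chemical environment within a cutoff
# sphere. Radial (two-body, Gaussian shells) and angular (three-body,
# cosine-modulated) functions, resolved by neighbor element combination, with
# analytic jacobians w.r.t. all Cartesian coordinates for force evaluation.

#' Descriptor parameterization
#'
#' Defines the symmetry-function set used to featurize atomic environments.
#' Radial functions G2 = sum_j exp(-eta (r_ij - r_s)^2) fc(r_ij) are generated
#' for every (eta, r_s) pair and every neighbor element; angular functions
#' G4 = 2^(1-zeta) sum_{j<k} (1 + lambda cos theta)^zeta
#' exp(-eta (r_ij^2 + r_ik^2 + r_jk^2)) fc(r_ij) fc(r_ik) fc(r_jk)
#' for every (eta, zeta, lambda) triple and unordered neighbor-element pair.
#' The descriptor length is fixed per central element once parameters are set.
#'
#' @param elements Character vector of element symbols the model must cover.
#' @param cutoff Cutoff radius in Angstrom (default 4.0).
#' @param radial_eta Radial Gaussian widths, 1/Angstrom^2.
#' @param radial_rs Radial shifts, Angstrom (recycled against radial_eta).
#' @param angular_eta Angular Gaussian widths, 1/Angstrom^2.
#' @param angular_zeta Angular sharpness exponents (>= 1).
#' @param angular_lambda Angular phase, +1 or -1.
#' @return An object of class \code{descriptor_params}.
#' @export
descriptor_params <- function(elements,
                              cutoff = 4.0,
                              radial_eta = c(0, 0.04, 0.1, 0.3, 1.0),
                              radial_rs = 0,
                              angular_eta = c(1e-4, 0.01),
                              angular_zeta = c(1, 4),
                              angular_lambda = c(-1, 1)) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(angular_zeta < 1)) stop("zeta must be >= 1")
  if (!all(angular_lambda %in% c(-1, 1))) stop("lambda must be +1 or -1")
  elements <- sort(unique(as.character(elements)))
  radial <- data.frame(eta = radial_eta,
                       rs = rep_len(radial_rs, length(radial_eta)))
  angular <- expand.grid(eta = angular_eta, zeta = angular_zeta,
                         lambda = angular_lambda)
  # Unordered neighbor element pairs for the angular block.
  pairs <- list()
  for (i in seq_along(elements)) {
    for (j in i:length(elements)) {
      pairs[[length(pairs) + 1L]] <- c(elements[i], elements[j])
    }
  }
  obj <- structure(
    list(elements = elements, cutoff = cutoff,
         radial = radial, angular = angular, element_pairs = pairs),
    class = "descriptor_params")
  obj$length <- length(elements) * nrow(radial) + length(pairs) * nrow(angular)
  obj
}

#' @export
print.descriptor_params <- function(x, ...) {
  cat("<descriptor_params> elements:", paste(x$elements, collapse = " "),
      "| cutoff:", x$cutoff, "A |", nrow(x$radial), "radial x",
      length(x$elements), "elements +", nrow(x$angular), "angular x",
      length(x$element_pairs), "pairs =", x$length, "components\n")
  invisible(x)
}

#' Cosine cutoff function
#'
#' fc(r) = 0.5 (cos(pi r / rc) + 1) for r < rc, 0 beyond. Smooth, monotonically
#' decreasing, with value and first derivative continuous at the cutoff.
#'
#' @param r Distances (Angstrom), non-negative.
#' @param rc Cutoff radius (Angstrom), positive.
#' @return Dimensionless values in [0, 1].
#' @export
cutoff_function <- function(r, rc) {
  if (any(r < 0)) stop("r must be non-negative")
  if (rc <= 0) stop("cutoff radius must be positive")
  ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)
}

# d fc / d r
cutoff_function_deriv <- function(r, rc) {
  ifelse(r < rc, -0.5 * pi / rc * sin(pi * r / rc), 0)
}

#' Radial symmetry function for one atom (reference implementation)
#'
#' Plain scalar sum over neighbors of the requested element. The vectorized
#' path in \code{\link{featurize}} is tested against this form.
#'
#' @param config An \code{atomic_config}.
#' @param atom_index Central atom (1-based).
#' @param eta Gaussian width (1/Angstrom^2).
#' @param rs Gaussian shift (Angstrom).
#' @param rc Cutoff radius (Angstrom).
#' @param neighbor_element Element symbol the sum is restricted to.
#' @return Dimensionless scalar.
#' @export
radial_function <- function(config, atom_index, eta, rs, rc, neighbor_element) {
  pos <- config$positions
  total <- 0
  for (j in seq_len(nrow(pos))) {
    if (j == atom_index || config$elements[j] != neighbor_element) next
    r <- sqrt(sum((pos[j, ] - pos[atom_index, ])^2))
    if (r < rc) total <- total + exp(-eta * (r - rs)^2) * cutoff_function(r, rc)
  }
  total
}

#' Angular symmetry function for one atom (reference implementation)
#'
#' Scalar triple loop over neighbor pairs of the requested elements; used as
#' the brute-force oracle for the vectorized featurizer.
#'
#' @inheritParams radial_function
#' @param zeta Sharpness exponent (>= 1).
#' @param lambda Phase, +1 or -1.
#' @param element_pair Character vector of two neighbor element symbols
#'   (unordered).
#' @return Dimensionless scalar.
#' @export
angular_function <- function(config, atom_index, eta, zeta, lambda, rc,
                             element_pair) {
  pos <- config$positions
  el <- config$elements
  n <- nrow(pos)
  ep <- sort(element_pair)
  total <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j >= k || j == atom_index || k == atom_index) next
      if (!identical(sort(c(el[j], el[k])), ep)) next
      rij <- sqrt(sum((pos[j, ] - pos[atom_index, ])^2))
      rik <- sqrt(sum((pos[k, ] - pos[atom_index, ])^2))
      rjk <- sqrt(sum((pos[k, ] - pos[j, ])^2))
      if (rij >= rc || rik >= rc || rjk >= rc) next
      cost <- sum((pos[j, ] - pos[atom_index, ]) *
                  (pos[k, ] - pos[atom_index, ])) / (rij * rik)
      total <- total + (1 + lambda * cost)^zeta *
        exp(-eta * (rij^2 + rik^2 + rjk^2)) *
        cutoff_function(rij, rc) * cutoff_function(rik, rc) *
        cutoff_function(rjk, rc)
    }
  }
  2^(1 - zeta) * total
}

#' Featurize a configuration
#'
#' Computes one fixed-length symmetry-function vector per atom and, optionally,
#' the analytic jacobian of every component with respect to all Cartesian
#' coordinates (needed for forces).
#'
#' @param config An \code{atomic_config}.
#' @param params A \code{descriptor_params}.
#' @param jacobian If TRUE, return per-atom jacobian matrices
#'   (components x 3N, units 1/Angstrom).
#' @return A list with one entry per atom: \code{element}, \code{values}
#'   (length \code{params$length}) and, when requested, \code{jacobian}.
#' @export
featurize <- function(config, params, jacobian = FALSE) {
  pos <- config$positions
  el <- config$elements
  n <- nrow(pos)
  unknown <- setdiff(unique(el), params$elements)
  if (length(unknown)) {
    stop("element(s) not covered by descriptor parameters: ",
         paste(unknown, collapse = ", "))
  }
  rc <- params$cutoff
  dm <- if (n > 1) distance_matrix(pos) else matrix(0, 1, 1)
  if (n > 1 && min(dm[upper.tri(dm)]) < 1e-8) {
    stop("degenerate geometry: coincident atoms")
  }
  n_rad <- nrow(params$radial)
  n_ang <- nrow(params$angular)
  n_el <- length(params$elements)
  n_pairs <- length(params$element_pairs)
  pair_key <- vapply(params$element_pairs, paste, "", collapse = ":")
  out <- vector("list", n)

  for (i in seq_len(n)) {
    G <- numeric(params$length)
    J <- if (jacobian) matrix(0, params$length, 3L * n) else NULL
    neigh <- which(dm[i, ] < rc & seq_len(n) != i)

    # ---- radial block ----
    for (e in seq_len(n_el)) {
      js <- neigh[el[neigh] == params$elements[e]]
      base <- (e - 1L) * n_rad
      if (!length(js)) next
      r <- dm[i, js]
      fc <- cutoff_function(r, rc)
      dfc <- cutoff_function_deriv(r, rc)
      for (p in seq_len(n_rad)) {
        eta <- params$radial$eta[p]; rs <- params$radial$rs[p]
        gauss <- exp(-eta * (r - rs)^2)
        G[base + p] <- sum(gauss * fc)
        if (jacobian) {
          # d/dr of each neighbor term
          dterm <- gauss * (dfc - 2 * eta * (r - rs) * fc)
          for (m in seq_along(js)) {
            j <- js[m]
            u <- (pos[j, ] - pos[i, ]) / r[m]  # d r_ij / d R_j
            cj <- 3L * (j - 1L) + 1:3
            ci <- 3L * (i - 1L) + 1:3
            J[base + p, cj] <- J[base + p, cj] + dterm[m] * u
            J[base + p, ci] <- J[base + p, ci] - dterm[m] * u
          }
        }
      }
    }

    # ---- angular block ----
    ang_base <- n_el * n_rad
    if (length(neigh) >= 2) {
      eta_a <- params$angular$eta
      zeta_a <- params$angular$zeta
      lam_a <- params$angular$lambda
      pref <- 2^(1 - zeta_a)
      nb <- length(neigh)
      for (a in seq_len(nb - 1L)) {
        for (b in (a + 1L):nb) {
          j <- neigh[a]; k <- neigh[b]
          rjk <- dm[j, k]
          if (rjk >= rc) next
          key <- paste(sort(c(el[j], el[k])), collapse = ":")
          pidx <- match(key, pair_key)
          rij <- dm[i, j]; rik <- dm[i, k]
          u <- pos[j, ] - pos[i, ]; v <- pos[k, ] - pos[i, ]
          w <- pos[k, ] - pos[j, ]
          cost <- sum(u * v) / (rij * rik)
          fij <- cutoff_function(rij, rc); fik <- cutoff_function(rik, rc)
          fjk <- cutoff_function(rjk, rc)
          dfij <- cutoff_function_deriv(rij, rc)
          dfik <- cutoff_function_deriv(rik, rc)
          dfjk <- cutoff_function_deriv(rjk, rc)
          gauss <- exp(-eta_a * (rij^2 + rik^2 + rjk^2))
          onepl <- 1 + lam_a * cost
          # guard 0^0 when zeta = 1 and cos term cancels exactly
          Apow <- ifelse(onepl <= 0, 0, onepl^zeta_a)
          fcs <- fij * fik * fjk
          terms <- pref * Apow * gauss * fcs
          rows <- ang_base + (pidx - 1L) * n_ang + seq_len(n_ang)
          G[rows] <- G[rows] + terms
          if (jacobian) {
            # derivative pieces shared by all parameter combinations
            uh <- u / rij; vh <- v / rik; wh <- w / rjk
            dc_dj <- v / (rij * rik) - cost * u / rij^2   # d cos / d R_j
            dc_dk <- u / (rij * rik) - cost * v / rik^2   # d cos / d R_k
            dc_di <- -(dc_dj + dc_dk)
            Apow1 <- ifelse(onepl <= 0, ifelse(zeta_a == 1, 1, 0),
                            onepl^(zeta_a - 1))
            cA <- pref * gauss * fcs * zeta_a * lam_a * Apow1  # coef of dcos
            cB <- pref * Apow * gauss                          # coef of d(fc,gauss)
            # distance derivative factors per edge
            gij <- cB * (dfij * fik * fjk - 2 * eta_a * rij * fcs)
            gik <- cB * (fij * dfik * fjk - 2 * eta_a * rik * fcs)
            gjk <- cB * (fij * fik * dfjk - 2 * eta_a * rjk * fcs)
            ci <- 3L * (i - 1L) + 1:3
            cj <- 3L * (j - 1L) + 1:3
            ck <- 3L * (k - 1L) + 1:3
            # accumulate: outer(param-vector, 3-vector)
            J[rows, cj] <- J[rows, cj] + outer(cA, dc_dj) +
              outer(gij, uh) - outer(gjk, wh)
            J[rows, ck] <- J[rows, ck] + outer(cA, dc_dk) +
              outer(gik, vh) + outer(gjk, wh)
            J[rows, ci] <- J[rows, ci] + outer(cA, dc_di) -
              outer(gij, uh) - outer(gik, vh)
          }
        }
      }
    }
    out[[i]] <- list(element = el[i], values = G, jacobian = J)
  }
  out
}
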