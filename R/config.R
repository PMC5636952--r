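#' Atomic configuration
#'
#' A single molecular geometry: element symbols, Cartesian positions and
#' optional reference labels (energy, forces, dipole moment, total charge).
#' This is the basic record exchanged between every stage of the pipeline:
#' surrogate reference calculators label it, training consumes it, molecular
#' dynamics propagates it.
#'
#' @param elements Character vector of element symbols (length N).
#' @param positions N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param energy Optional reference energy (kcal/mol).
#' @param forces Optional N x 3 matrix of reference forces (kcal/mol/Angstrom).
#' @param dipole Optional length-3 reference dipole vector (Debye).
#' @param total_charge Optional reference total charge (e).
#' @return An object of class \code{atomic_config}.
#' @export
atomic_config <- function(elements, positions, energy = NULL, forces = NULL,
                          dipole = NULL, total_charge = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L || nrow(positions) != length(elements)) {
    stop("positions must be an N x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == dim(positions))) {
      stop("forces must match positions in shape")
    }
  }
  if (!is.null(dipole) && length(dipole) != 3L) {
    stop("dipole must be a length-3 vector")
  }
  structure(
    list(elements = as.character(elements), positions = positions,
         energy = energy, forces = forces,
         dipole = if (is.null(dipole)) NULL else as.numeric(dipole),
         total_charge = total_charge),
    class = "atomic_config")
}

#' @export
print.atomic_config <- function(x, ...) {
  cat("<atomic_config> ", length(x$elements), " atoms (",
      paste(names(table(x$elements)), table(x$elements), sep = "",
            collapse = " "), ")",
      if (!is.null(x$energy)) sprintf("  E = %.4f kcal/mol", x$energy),
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config An \code{atomic_config}.
#' @return Integer atom count.
#' @export
n_atoms <- function(config) length(config$elements)

#' Center of mass of a configuration
#'
#' Uses standard atomic masses.
#'
#' @param config An \code{atomic_config}.
#' @return Length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(config) {
  m <- atomic_masses(config$elements)
  colSums(config$positions * m) / sum(m)
}

# Pairwise distance matrix (dense; desk-scale molecules are small).
distance_matrix <- function(positions) {
  as.matrix(stats::dist(positions))
}

#' Rigidly transform a configuration
#'
#' Applies a rotation followed by a translation to positions (and forces,
#' if present; forces rotate but do not translate).
#'
#' @param config An \code{atomic_config}.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation Length-3 shift vector in Angstrom (default zero).
#' @return The transformed \code{atomic_config}.
#' @export
transform_config <- function(config, rotation = diag(3),
                             translation = c(0, 0, 0)) {
  config$positions <- config$positions %*% t(rotation) +
    matrix(translation, n_atoms(config), 3, byrow = TRUE)
  if (!is.null(config$forces)) config$forces <- config$forces %*% t(rotation)
  if (!is.null(config$dipole)) config$dipole <- drop(rotation %*% config$dipole)
  config
}

# Rotation matrix about a unit axis by angle (radians); Rodrigues formula.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
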