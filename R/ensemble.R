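# Committee of J independently initialized HDNNPs sharing one descriptor
# parameterization. Predictions are the arithmetic mean of the members; the
# disagreement (population standard deviation of member energies) serves as
# an extrapolation detector during adaptive sampling.

#' Build an HDNNP ensemble
#'
#' @param members List of J >= 2 \code{hdnnp} models with identical
#'   descriptor parameterizations, typically differing only in their
#'   initialization seed.
#' @return An \code{hdnnp_ensemble}.
#' @export
hdnnp_ensemble <- function(members) {
  if (length(members) < 2) stop("an ensemble needs at least 2 members")
  len <- vapply(members, function(m) m$descriptor_params$length, 0)
  if (length(unique(len)) != 1) {
    stop("members must share the descriptor parameterization")
  }
  structure(list(members = members, J = length(members)),
            class = "hdnnp_ensemble")
}

#' Create an ensemble of freshly initialized HDNNPs
#'
#' @param params A \code{descriptor_params}.
#' @param J Number of members (>= 2).
#' @param hidden Hidden layer sizes.
#' @param seed Base seed; member j uses \code{seed + j}.
#' @return An \code{hdnnp_ensemble}.
#' @export
new_ensemble <- function(params, J = 3, hidden = c(35, 35), seed = 1L) {
  hdnnp_ensemble(lapply(seq_len(J), function(j)
    hdnnp(params, hidden = hidden, seed = seed + j)))
}

#' @export
print.hdnnp_ensemble <- function(x, ...) {
  cat("<hdnnp_ensemble> J =", x$J, "members\n")
  invisible(x)
}

#' Ensemble energy, forces and uncertainty
#'
#' Energy and forces are the arithmetic means of the member predictions; the
#' uncertainty is the population (1/J) standard deviation of the member
#' energies. A per-atom-normalized variant and a force-disagreement measure
#' (maximum over atoms of the member force spread) are available for
#' size-consistent thresholds and fragment selection.
#'
#' @param calc An \code{hdnnp_ensemble}.
#' @param config An \code{atomic_config}.
#' @param forces Include averaged forces.
#' @param dipole Ignored (ensembles model the potential only).
#' @return List with \code{energy}, \code{forces}, \code{uncertainty}
#'   (kcal/mol), \code{member_energies}.
#' @export
calc_evaluate.hdnnp_ensemble <- function(calc, config, forces = TRUE,
                                         dipole = FALSE) {
  features <- featurize(config, calc$members[[1]]$descriptor_params,
                        jacobian = forces)
  E <- numeric(calc$J)
  Fsum <- NULL
  Flist <- if (forces) vector("list", calc$J)
  for (j in seq_len(calc$J)) {
    pred <- tryCatch(
      hdnnp_predict(calc$members[[j]], config, forces = forces,
                    features = features),
      error = function(e) stop("ensemble member ", j, " failed: ",
                               conditionMessage(e)))
    E[j] <- pred$energy
    if (forces) {
      Flist[[j]] <- pred$forces
      Fsum <- if (is.null(Fsum)) pred$forces else Fsum + pred$forces
    }
  }
  out <- list(energy = mean(E),
              uncertainty = sqrt(mean((E - mean(E))^2)),
              member_energies = E)
  if (forces) {
    out$forces <- Fsum / calc$J
    out$member_forces <- Flist
  }
  out
}

#' Ensemble mean energy
#' @param ens An \code{hdnnp_ensemble}.
#' @param config An \code{atomic_config}.
#' @return Mean member energy (kcal/mol).
#' @export
ensemble_energy <- function(ens, config) {
  calc_evaluate(ens, config, forces = FALSE)$energy
}

#' Ensemble mean forces
#' @inheritParams ensemble_energy
#' @return N x 3 matrix (kcal/mol/Angstrom).
#' @export
ensemble_forces <- function(ens, config) {
  calc_evaluate(ens, config, forces = TRUE)$forces
}

#' Ensemble disagreement
#'
#' Population standard deviation of member energies; optionally normalized
#' per atom, or the force-based variant (maximum over atoms of the root mean
#' squared member deviation of the force vector).
#'
#' @inheritParams ensemble_energy
#' @param per_atom Divide the energy spread by the atom count.
#' @param measure "energy" (default) or "force".
#' @return Non-negative scalar (kcal/mol, or kcal/mol/Angstrom for
#'   \code{measure = "force"}).
#' @export
ensemble_uncertainty <- function(ens, config, per_atom = FALSE,
                                 measure = c("energy", "force")) {
  measure <- match.arg(measure)
  res <- calc_evaluate(ens, config, forces = measure == "force")
  if (measure == "energy") {
    u <- res$uncertainty
    if (per_atom) u <- u / n_atoms(config)
    return(u)
  }
  Fbar <- res$forces
  dev2 <- Reduce(`+`, lapply(res$member_forces, function(Fm)
    rowSums((Fm - Fbar)^2))) / ens$J
  sqrt(max(dev2))
}
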