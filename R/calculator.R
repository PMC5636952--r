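# A "calculator" is anything that maps an atomic_config to energy, forces and
# (optionally) a dipole moment and total charge: an HDNNP, an ensemble, a
# surrogate reference potential, or a plain R function. Molecular dynamics,
# adaptive sampling and spectra all consume this one interface.

#' Evaluate a calculator on a configuration
#'
#' Generic entry point used by the MD engine, the sampling loop and the
#' labeling helpers.
#'
#' @param calc A calculator: \code{hdnnp}, \code{hdnnp_ensemble},
#'   \code{surrogate_calculator} or \code{function_calculator}.
#' @param config An \code{atomic_config}.
#' @param forces If TRUE include forces.
#' @param dipole If TRUE include the dipole vector (Debye) and total charge
#'   (e) when the calculator can provide them.
#' @return List with \code{energy} and optionally \code{forces},
#'   \code{dipole}, \code{total_charge}, \code{uncertainty} (ensembles only).
#' @export
calc_evaluate <- function(calc, config, forces = TRUE, dipole = FALSE) {
  UseMethod("calc_evaluate")
}

#' @export
calc_evaluate.hdnnp <- function(calc, config, forces = TRUE, dipole = FALSE) {
  hdnnp_predict(calc, config, forces = forces)
}

#' @export
calc_evaluate.function_calculator <- function(calc, config, forces = TRUE,
                                              dipole = FALSE) {
  calc$fn(config)
}

#' Wrap a plain function as a calculator
#'
#' @param fn Function taking an \code{atomic_config} and returning a list with
#'   \code{energy}, \code{forces} and optionally \code{dipole},
#'   \code{total_charge}.
#' @return A \code{function_calculator}.
#' @export
function_calculator <- function(fn) {
  structure(list(fn = fn), class = "function_calculator")
}

#' Label a configuration with a reference calculator
#'
#' Runs the calculator and attaches energy, forces, dipole and total charge as
#' reference labels on the configuration.
#'
#' @param calc A calculator (typically a surrogate reference).
#' @param config An \code{atomic_config}.
#' @return The labeled \code{atomic_config}.
#' @export
label_config <- function(calc, config) {
  res <- calc_evaluate(calc, config, forces = TRUE, dipole = TRUE)
  config$energy <- res$energy
  config$forces <- res$forces
  if (!is.null(res$dipole)) config$dipole <- res$dipole
  if (!is.null(res$total_charge)) config$total_charge <- res$total_charge
  config
}
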