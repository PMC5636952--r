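# Classical molecular dynamics over any calculator. Velocity Verlet for NVE;
# Langevin dynamics via the BAOAB splitting (one force evaluation per step,
# reduces exactly to velocity Verlet at zero friction); optional Berendsen
# weak coupling. Internal units: Angstrom, fs, kcal/mol, amu.

#' Molecular dynamics settings
#'
#' @param timestep Integration timestep in fs (default 0.5).
#' @param temperature Target temperature in K.
#' @param thermostat One of "none" (NVE), "langevin", "berendsen".
#' @param friction Langevin friction in 1/fs (default 0.01, gentle coupling so
#'   spectral bands are not over-broadened).
#' @param tau Berendsen coupling time in fs.
#' @param n_steps Number of production steps.
#' @param equilibration_steps Steps discarded before recording.
#' @param stride Record every \code{stride}-th frame.
#' @param seed Integer RNG seed (velocities and Langevin noise).
#' @return An object of class \code{md_config}.
#' @export
md_config <- function(timestep = 0.5, temperature = 300,
                      thermostat = c("langevin", "none", "berendsen"),
                      friction = 0.01, tau = 100, n_steps = 1000,
                      equilibration_steps = 0, stride = 1, seed = 1L) {
  thermostat <- match.arg(thermostat)
  if (timestep <= 0) stop("timestep must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  if (thermostat == "langevin" && friction <= 0) stop("friction must be > 0")
  if (thermostat == "berendsen" && tau <= 0) stop("tau must be > 0")
  structure(list(timestep = timestep, temperature = temperature,
                 thermostat = thermostat, friction = friction, tau = tau,
                 n_steps = as.integer(n_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "md_config")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian velocities at temperature T with the center-of-mass momentum
#' removed.
#'
#' @param config An \code{atomic_config}.
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return N x 3 matrix of velocities (Angstrom/fs).
#' @export
initialize_velocities <- function(config, temperature, seed = 1L) {
  n <- n_atoms(config)
  if (temperature == 0) return(matrix(0, n, 3))
  m <- atomic_masses(config$elements)
  old <- .Random.seed_save()
  set.seed(seed)
  kT <- nnpir_constants$kB * temperature / nnpir_constants$kcal_per_internal
  v <- matrix(stats::rnorm(3L * n), n, 3) * sqrt(kT / m)
  .Random.seed_restore(old)
  # remove center-of-mass momentum
  p <- colSums(v * m)
  sweep(v, 2, p / sum(m))
}

kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * rowSums(velocities^2)) * nnpir_constants$kcal_per_internal
}

# dof: 3N-3 when the center-of-mass momentum is conserved (NVE, Berendsen);
# a Langevin bath couples to all 3N degrees of freedom.
instantaneous_temperature <- function(velocities, masses, dof = NULL) {
  n <- nrow(velocities)
  if (is.null(dof)) dof <- max(3L * n - 3L, 1L)
  2 * kinetic_energy(velocities, masses) / (dof * nnpir_constants$kB)
}

# acceleration in Angstrom/fs^2 from forces in kcal/mol/Angstrom
.accel <- function(forces, masses) {
  forces / (masses * nnpir_constants$kcal_per_internal)
}

#' One velocity-Verlet step
#'
#' Plain NVE update; time-reversible and symplectic. \code{state} carries
#' \code{config}, \code{velocities} and the current \code{forces}.
#'
#' @param state List with \code{config}, \code{velocities}, \code{forces}.
#' @param calculator Any calculator accepted by \code{\link{calc_evaluate}}.
#' @param dt Timestep in fs.
#' @return Updated state (with new \code{forces} and \code{energy}).
#' @export
velocity_verlet_step <- function(state, calculator, dt) {
  m <- atomic_masses(state$config$elements)
  v <- state$velocities + 0.5 * dt * .accel(state$forces, m)
  state$config$positions <- state$config$positions + dt * v
  res <- calc_evaluate(calculator, state$config, forces = TRUE)
  if (!all(is.finite(res$forces))) {
    stop("non-finite forces encountered during propagation")
  }
  state$velocities <- v + 0.5 * dt * .accel(res$forces, m)
  state$forces <- res$forces
  state$energy <- res$energy
  state
}

#' Run molecular dynamics
#'
#' Propagates a configuration with velocity Verlet (BAOAB splitting when the
#' Langevin thermostat is on), recording positions, energies and, when a
#' dipole source is available, the molecular dipole every recorded frame.
#' Deterministic for a fixed seed.
#'
#' @param calculator Energy/force source (model, ensemble or surrogate).
#' @param config Starting \code{atomic_config}.
#' @param mdcfg An \code{\link{md_config}}.
#' @param velocities Optional starting velocities (otherwise drawn at the
#'   target temperature from the seed).
#' @param dipole_calc Optional dipole source evaluated on every recorded
#'   frame: a \code{dipole_model} or any calculator returning \code{dipole}.
#' @param stop_fn Optional function(config, info) -> logical; when it returns
#'   TRUE propagation halts and the offending configuration is stored in
#'   \code{trajectory$stopped}. \code{info} holds \code{energy} and (for
#'   ensembles) \code{uncertainty}.
#' @return A \code{trajectory} object.
#' @export
run_md <- function(calculator, config, mdcfg, velocities = NULL,
                   dipole_calc = NULL, stop_fn = NULL) {
  m <- atomic_masses(config$elements)
  n <- n_atoms(config)
  old <- .Random.seed_save()
  set.seed(mdcfg$seed)
  on.exit(.Random.seed_restore(old))
  if (is.null(velocities)) {
    velocities <- initialize_velocities(config, mdcfg$temperature,
                                        seed = mdcfg$seed + 7L)
  }
  dt <- mdcfg$timestep
  lang <- mdcfg$thermostat == "langevin"
  if (lang) {
    c1 <- exp(-mdcfg$friction * dt)
    kT <- nnpir_constants$kB * mdcfg$temperature /
      nnpir_constants$kcal_per_internal
    sig <- sqrt(kT / m) * sqrt(1 - c1^2)
  }
  res <- calc_evaluate(calculator, config, forces = TRUE)
  dof <- if (lang) 3L * n else max(3L * n - 3L, 1L)
  total <- mdcfg$equilibration_steps + mdcfg$n_steps
  nrec <- if (mdcfg$n_steps > 0)
    length(seq(1L, mdcfg$n_steps, by = mdcfg$stride)) else 0L
  times <- numeric(nrec)
  frames <- vector("list", nrec)
  vels <- vector("list", nrec)
  energies <- numeric(nrec)
  temps <- numeric(nrec)
  dipoles <- matrix(NA_real_, nrec, 3)
  charges <- vector("list", nrec)
  have_dip <- !is.null(dipole_calc)
  rec <- 0L
  stopped <- NULL
  step <- 0L
  while (step < total) {
    step <- step + 1L
    # B: half kick
    v <- velocities + 0.5 * dt * .accel(res$forces, m)
    if (lang) {
      # A-O-A
      config$positions <- config$positions + 0.5 * dt * v
      v <- c1 * v + sig * matrix(stats::rnorm(3L * n), n, 3)
      config$positions <- config$positions + 0.5 * dt * v
    } else {
      config$positions <- config$positions + dt * v
    }
    res <- calc_evaluate(calculator, config, forces = TRUE)
    if (!all(is.finite(res$forces))) {
      stopped <- list(step = step, config = config, reason = "non-finite")
      warning("non-finite forces at step ", step, "; returning partial trajectory")
      break
    }
    velocities <- v + 0.5 * dt * .accel(res$forces, m)
    if (mdcfg$thermostat == "berendsen" && mdcfg$temperature > 0) {
      Tn <- instantaneous_temperature(velocities, m)
      if (Tn > 0) {
        lam <- sqrt(1 + dt / mdcfg$tau * (mdcfg$temperature / Tn - 1))
        velocities <- velocities * lam
      }
    }
    prod_step <- step - mdcfg$equilibration_steps
    if (prod_step >= 1L && (prod_step - 1L) %% mdcfg$stride == 0L) {
      rec <- rec + 1L
      times[rec] <- prod_step * dt
      frames[[rec]] <- config$positions
      vels[[rec]] <- velocities
      energies[rec] <- res$energy
      temps[rec] <- instantaneous_temperature(velocities, m, dof = dof)
      if (have_dip) {
        dres <- calc_evaluate(dipole_calc, config, forces = FALSE,
                              dipole = TRUE)
        dipoles[rec, ] <- dres$dipole
        if (!is.null(dres$charges)) charges[[rec]] <- dres$charges
      }
    }
    if (!is.null(stop_fn)) {
      info <- list(energy = res$energy, step = step,
                   uncertainty = res$uncertainty)
      if (isTRUE(stop_fn(config, info))) {
        stopped <- list(step = step, config = config, info = info,
                        reason = "stop_fn")
        break
      }
    }
  }
  keep <- seq_len(rec)
  structure(list(times = times[keep], frames = frames[keep],
                 elements = config$elements, velocities = vels[keep],
                 energies = energies[keep], temperatures = temps[keep],
                 dipoles = if (have_dip) dipoles[keep, , drop = FALSE] else NULL,
                 charges = if (have_dip && rec > 0 &&
                               !is.null(charges[[1]])) charges[keep],
                 dt = dt * mdcfg$stride, seed = mdcfg$seed,
                 stopped = stopped,
                 final = list(config = config, velocities = velocities)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "frames, dt =", x$dt, "fs",
      if (!is.null(x$dipoles)) "(dipoles recorded)",
      if (!is.null(x$stopped)) sprintf("[stopped at step %d]", x$stopped$step),
      "\n")
  invisible(x)
}
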