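# Infrared spectra from molecular dynamics: the IR intensity is the Fourier
# transform of the time autocorrelation of the dipole-moment derivative,
# I(omega) ~ integral <mu_dot(t) . mu_dot(t+tau)> e^(-i omega tau) d tau.
# Also: geometry optimization and normal-mode (harmonic) analysis with static
# intensities from the dipole model, for cross-checking MD peak positions.

#' Spectrum settings
#'
#' @param max_lag_fraction ACF length as a fraction of the trajectory
#'   (default 0.5).
#' @param window Lag window: "hann" (default) or "none".
#' @param zero_padding Zero-padding factor (>= 1, default 4); refines the
#'   frequency grid by interpolation without adding information.
#' @param mode Intensity from the "magnitude" (default, non-negative by
#'   construction) or "real" part of the transform.
#' @param derivative "central_difference" of recorded mu(t) (default) or
#'   "charge_velocity" (q_i v_i chain rule; requires charges+velocities).
#' @param normalize Scale intensities to a maximum of 1 (default TRUE).
#' @return An object of class \code{spectrum_config}.
#' @export
spectrum_config <- function(max_lag_fraction = 0.5,
                            window = c("hann", "none"), zero_padding = 4,
                            mode = c("magnitude", "real"),
                            derivative = c("central_difference",
                                           "charge_velocity"),
                            normalize = TRUE) {
  if (zero_padding < 1) stop("zero_padding must be >= 1")
  if (max_lag_fraction <= 0 || max_lag_fraction >= 1) {
    stop("max_lag_fraction must be in (0, 1)")
  }
  structure(list(max_lag_fraction = max_lag_fraction,
                 window = match.arg(window),
                 zero_padding = zero_padding, mode = match.arg(mode),
                 derivative = match.arg(derivative),
                 normalize = isTRUE(normalize)),
            class = "spectrum_config")
}

#' Time derivative of the dipole series
#'
#' Central differences on the interior points (exact for linear signals,
#' O(dt^2) otherwise); the two endpoints are dropped.
#'
#' @param dipoles M x 3 matrix of dipole vectors (Debye) on a uniform grid.
#' @param dt Time spacing in fs.
#' @return (M-2) x 3 matrix of derivatives (Debye/fs).
#' @export
dipole_derivative <- function(dipoles, dt) {
  dipoles <- as.matrix(dipoles)
  m <- nrow(dipoles)
  if (m < 3) stop("need at least 3 frames for a central difference")
  if (dt <= 0) stop("dt must be positive")
  (dipoles[3:m, , drop = FALSE] - dipoles[1:(m - 2), , drop = FALSE]) /
    (2 * dt)
}

#' Vector autocorrelation function
#'
#' C(tau_k) = mean_t mu_dot(t) . mu_dot(t + tau_k), lag-normalized (each lag
#' divided by its number of contributing products). FFT-based.
#'
#' @param series M x 3 (or M x d) matrix.
#' @param max_lag Largest lag index (< M).
#' @return Numeric vector C(0..max_lag).
#' @export
autocorrelation <- function(series, max_lag) {
  series <- as.matrix(series)
  m <- nrow(series)
  if (max_lag >= m) stop("max_lag must be smaller than the series length")
  npad <- stats::nextn(2L * m, 2)
  acf_sum <- numeric(max_lag + 1L)
  for (d in seq_len(ncol(series))) {
    x <- c(series[, d], rep(0, npad - m))
    ft <- stats::fft(x)
    cc <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / npad
    acf_sum <- acf_sum + cc[seq_len(max_lag + 1L)]
  }
  acf_sum / (m - 0:max_lag)
}

#' IR spectrum from a trajectory
#'
#' Computes the dipole time derivative, its autocorrelation up to
#' \code{max_lag_fraction} of the trajectory, applies the lag window,
#' zero-pads, Fourier transforms, and returns intensity (normalized to a
#' maximum of 1) over an ascending wavenumber axis.
#'
#' @param traj A \code{trajectory} with recorded dipoles, or a list with
#'   \code{dipoles} (matrix, Debye) and \code{dt} (fs).
#' @param cfg A \code{\link{spectrum_config}}.
#' @return An object of class \code{ir_spectrum}: list with
#'   \code{wavenumber} (cm^-1, ascending), \code{intensity} (normalized),
#'   and \code{resolution} (grid spacing, cm^-1).
#' @export
ir_spectrum <- function(traj, cfg = spectrum_config()) {
  if (is.null(traj$dipoles)) {
    stop("trajectory has no recorded dipoles; ",
         "run the dynamics with dipole recording enabled")
  }
  dt <- traj$dt
  if (cfg$derivative == "charge_velocity") {
    mudot <- .charge_velocity_derivative(traj)
  } else {
    mudot <- dipole_derivative(traj$dipoles, dt)
  }
  m <- nrow(mudot)
  max_lag <- max(2L, floor(cfg$max_lag_fraction * m))
  C <- autocorrelation(mudot, max_lag)
  L <- length(C)
  w <- if (cfg$window == "hann") {
    0.5 * (1 + cos(pi * (0:max_lag) / max_lag))
  } else rep(1, L)
  # pad to a highly composite length so the FFT stays O(n log n)
  npad <- stats::nextn(cfg$zero_padding * L, c(2, 3, 5))
  padded <- c(C * w, rep(0, npad - L))
  ft <- stats::fft(padded)
  nyq <- floor(npad / 2)
  # even (cosine) transform of the one-sided ACF: 2 Re - C(0) term;
  # "magnitude" additionally folds in the quadrature part, guaranteeing
  # non-negativity
  intensity <- switch(cfg$mode,
                      magnitude = Mod(2 * ft - C[1] * w[1])[seq_len(nyq + 1L)],
                      real = pmax(2 * Re(ft) - C[1] * w[1], 0)[seq_len(nyq + 1L)])
  freq <- (0:nyq) / (npad * dt) * nnpir_constants$cm1_per_invfs
  if (cfg$normalize && max(intensity) > 0) {
    intensity <- intensity / max(intensity)
  }
  structure(list(wavenumber = freq, intensity = intensity,
                 resolution = freq[2] - freq[1],
                 acf = C, dt = dt),
            class = "ir_spectrum")
}

.charge_velocity_derivative <- function(traj) {
  if (is.null(traj$charges) || is.null(traj$velocities)) {
    stop("charge_velocity derivative needs recorded charges and velocities")
  }
  t(vapply(seq_along(traj$velocities), function(k)
    colSums(traj$velocities[[k]] * traj$charges[[k]]) *
      nnpir_constants$debye_per_eA,
    numeric(3)))
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat("<ir_spectrum>", length(x$wavenumber), "points, 0 -",
      round(max(x$wavenumber)), "cm^-1, resolution",
      signif(x$resolution, 3), "cm^-1\n")
  invisible(x)
}

#' Locate the strongest peak in a wavenumber range
#'
#' @param spectrum An \code{ir_spectrum}.
#' @param range Length-2 wavenumber window (cm^-1); default: everything
#'   above 10 cm^-1.
#' @return Wavenumber of the maximum intensity in the window (cm^-1).
#' @export
spectrum_peak <- function(spectrum, range = c(10, Inf)) {
  sel <- spectrum$wavenumber >= range[1] & spectrum$wavenumber <= range[2]
  if (!any(sel)) stop("no spectrum points in the requested range")
  spectrum$wavenumber[sel][which.max(spectrum$intensity[sel])]
}

#' Minimize a geometry on a calculator's surface
#'
#' BFGS on the analytic forces.
#'
#' @param calculator Any calculator.
#' @param config Starting \code{atomic_config}.
#' @param tol Convergence tolerance on the maximum force component
#'   (kcal/mol/Angstrom).
#' @param maxit Iteration budget.
#' @return The optimized \code{atomic_config} (attribute
#'   \code{max_force}).
#' @export
optimize_geometry <- function(calculator, config, tol = 1e-6, maxit = 500) {
  n <- n_atoms(config)
  shape <- function(x) matrix(x, n, 3)
  fn <- function(x) {
    c2 <- config; c2$positions <- shape(x)
    calc_evaluate(calculator, c2, forces = FALSE)$energy
  }
  gr <- function(x) {
    c2 <- config; c2$positions <- shape(x)
    -as.vector(calc_evaluate(calculator, c2, forces = TRUE)$forces)
  }
  res <- stats::optim(as.vector(config$positions), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  config$positions <- shape(res$par)
  mf <- max(abs(calc_evaluate(calculator, config, forces = TRUE)$forces))
  if (mf > tol) {
    # polish with a few steepest-descent steps if BFGS stalled early
    for (it in 1:200) {
      F <- calc_evaluate(calculator, config, forces = TRUE)$forces
      mf <- max(abs(F))
      if (mf <= tol) break
      config$positions <- config$positions + 1e-3 * F
    }
  }
  attr(config, "max_force") <- mf
  config
}

#' Normal-mode analysis with static IR intensities
#'
#' Mass-weighted Hessian by central finite differences of the analytic
#' forces at a (locally) optimized geometry; eigenvalues give harmonic
#' frequencies (negative eigenvalues are reported as negative wavenumbers,
#' not hidden). If a dipole source is supplied, static intensities
#' proportional to |d mu / d Q_k|^2 are attached.
#'
#' @param calculator Energy/force source.
#' @param config Geometry at (or near) a minimum; set \code{optimize} to
#'   refine it first.
#' @param dipole_calc Optional dipole source (\code{dipole_model} or
#'   surrogate).
#' @param step Finite-difference step (Angstrom).
#' @param optimize Optimize the geometry first (default TRUE).
#' @param force_tol Maximum force allowed at the expansion point.
#' @return List with \code{frequencies} (cm^-1, ascending; 3N values
#'   including near-zero translations/rotations), \code{modes} (mass-weighted
#'   eigenvectors), \code{intensities} (arbitrary units, or NULL),
#'   \code{config}.
#' @export
harmonic_analysis <- function(calculator, config, dipole_calc = NULL,
                              step = 1e-3, optimize = TRUE,
                              force_tol = 1e-4) {
  if (optimize) config <- optimize_geometry(calculator, config)
  F0 <- calc_evaluate(calculator, config, forces = TRUE)$forces
  if (max(abs(F0)) > force_tol) {
    warning("expansion point is not a stationary point (max |F| = ",
            signif(max(abs(F0)), 3), ")")
  }
  n <- n_atoms(config)
  m <- atomic_masses(config$elements)
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    for (d in 1:3) {
      cp <- config; cp$positions[a, d] <- cp$positions[a, d] + step
      Fp <- calc_evaluate(calculator, cp, forces = TRUE)$forces
      cm <- config; cm$positions[a, d] <- cm$positions[a, d] - step
      Fm <- calc_evaluate(calculator, cm, forces = TRUE)$forces
      # H[, col] = d(dE/dR)/dR_col = -dF/dR_col
      H[, 3 * (a - 1) + d] <- -as.vector(t(Fp - Fm)) / (2 * step)
    }
  }
  H <- (H + t(H)) / 2
  minv <- rep(1 / sqrt(m), each = 3)
  Hmw <- H * outer(minv, minv)
  eig <- eigen(Hmw, symmetric = TRUE)
  # eigenvalues in kcal/mol/A^2/amu -> angular frequency in rad/fs
  lam <- eig$values / nnpir_constants$kcal_per_internal
  freq <- sign(lam) * sqrt(abs(lam)) / (2 * pi) * nnpir_constants$cm1_per_invfs
  ord <- order(freq)
  freq <- freq[ord]
  modes <- eig$vectors[, ord, drop = FALSE]
  intensities <- NULL
  if (!is.null(dipole_calc)) {
    qstep <- 5e-3
    intensities <- vapply(seq_len(3 * n), function(k) {
      disp <- matrix(modes[, k] * minv, n, 3, byrow = TRUE)
      cp <- config; cp$positions <- cp$positions + qstep * disp
      cm <- config; cm$positions <- cm$positions - qstep * disp
      dp <- calc_evaluate(dipole_calc, cp, forces = FALSE, dipole = TRUE)$dipole
      dm <- calc_evaluate(dipole_calc, cm, forces = FALSE, dipole = TRUE)$dipole
      sum(((dp - dm) / (2 * qstep))^2)
    }, 0)
  }
  list(frequencies = freq, modes = modes, intensities = intensities,
       config = config)
}
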