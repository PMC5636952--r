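# Built-in toy systems: Morse/harmonic diatomics, a water-like triatomic with
# point charges, an n-alkane chain builder of arbitrary length (generic
# force-field-style parameters), and a protonatable 4-atom toy with a movable
# proton between two acceptor sites (a natural double well formed by two
# Morse terms). Each returns the starting geometry plus a matching surrogate
# reference calculator.

#' Built-in toy systems
#'
#' @return Character vector of system names accepted by
#'   \code{\link{surrogate_system}}.
#' @export
builtin_systems <- function() {
  c("morse_diatomic", "harmonic_diatomic", "water_like", "alkane_chain",
    "proton_toy")
}

#' Construct a named toy system
#'
#' @param system_name One of \code{\link{builtin_systems}()}.
#' @param ... Passed to the specific constructor (e.g. \code{n} for
#'   \code{alkane_chain}, \code{k}, \code{r0}, \code{De}, \code{a} for the
#'   diatomics, \code{locality} for the alkane).
#' @return List with \code{config} (an \code{atomic_config}) and
#'   \code{calculator} (a \code{surrogate_calculator}).
#' @export
surrogate_system <- function(system_name, ...) {
  switch(system_name,
         morse_diatomic = .sys_morse_diatomic(...),
         harmonic_diatomic = .sys_harmonic_diatomic(...),
         water_like = .sys_water(...),
         alkane_chain = .sys_alkane(...),
         proton_toy = .sys_proton_toy(...),
         stop("unknown system name: ", system_name))
}

.sys_morse_diatomic <- function(De = 150, a = 2.0, r0 = 1.13,
                                elements = c("C", "O"),
                                charges = c(0.2, -0.2)) {
  config <- atomic_config(elements, rbind(c(0, 0, 0), c(r0, 0, 0)))
  calc <- surrogate_pes(elements,
                        bonds = data.frame(i = 1, j = 2, type = "morse",
                                           k = NA, D = De, a = a, r0 = r0),
                        charges = charges, interaction_range = 3.0)
  list(config = config, calculator = calc)
}

.sys_harmonic_diatomic <- function(k = 1000, r0 = 1.1,
                                   elements = c("C", "O"),
                                   charges = c(0.3, -0.3)) {
  config <- atomic_config(elements, rbind(c(0, 0, 0), c(r0, 0, 0)))
  calc <- surrogate_pes(elements,
                        bonds = data.frame(i = 1, j = 2, type = "harmonic",
                                           k = k, D = NA, a = NA, r0 = r0),
                        charges = charges, interaction_range = 3.0)
  list(config = config, calculator = calc)
}

.sys_water <- function(k_oh = 1100, r0 = 0.96, k_ang = 70,
                       theta0 = 104.5 * pi / 180,
                       charges = c(-0.8, 0.4, 0.4),
                       bond_increments = NULL) {
  th <- theta0 / 2
  pos <- rbind(c(0, 0, 0),
               c(r0 * sin(th), r0 * cos(th), 0),
               c(-r0 * sin(th), r0 * cos(th), 0))
  elements <- c("O", "H", "H")
  calc <- surrogate_pes(
    elements,
    bonds = data.frame(i = c(1, 1), j = c(2, 3), type = "harmonic",
                       k = k_oh, D = NA, a = NA, r0 = r0),
    angles = data.frame(i = 2, j = 1, k = 3, ktheta = k_ang, theta0 = theta0),
    charges = charges, bond_increments = bond_increments,
    interaction_range = 3.0)
  list(config = atomic_config(elements, pos), calculator = calc)
}

# Zig-zag alkane geometry: backbone in the xz plane, hydrogens completing
# approximate tetrahedra. n carbons -> C_n H_{2n+2}.
.alkane_geometry <- function(n) {
  lcc <- 1.526; lch <- 1.09
  theta <- 112 * pi / 180
  s <- lcc * sin(theta / 2); cz <- lcc * cos(theta / 2)
  C <- cbind(seq_len(n) * s, 0, (seq_len(n) %% 2) * cz)
  elements <- rep("C", n)
  pos <- C
  add_h <- function(at, dir) {
    pos <<- rbind(pos, C[at, ] + lch * dir)
    elements <<- c(elements, "H")
  }
  tet <- 109.47 * pi / 180
  for (i in seq_len(n)) {
    nb <- c(if (i > 1) i - 1L, if (i < n) i + 1L)
    if (length(nb) == 2L) {
      u <- (C[nb[1], ] - C[i, ]) / lcc
      v <- (C[nb[2], ] - C[i, ]) / lcc
      bis <- -(u + v); bis <- bis / sqrt(sum(bis^2))
      perp <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                u[1] * v[2] - u[2] * v[1])
      perp <- perp / sqrt(sum(perp^2))
      half <- 107.8 / 2 * pi / 180
      add_h(i, bis * cos(half) + perp * sin(half))
      add_h(i, bis * cos(half) - perp * sin(half))
    } else if (length(nb) == 1L) {
      w <- (C[nb[1], ] - C[i, ]) / lcc
      e1 <- c(-w[3], 0, w[1]); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
              w[1] * e1[2] - w[2] * e1[1])
      for (phi in c(90, 210, 330) * pi / 180) {
        add_h(i, -w * cos(pi - tet) + sin(pi - tet) *
                (cos(phi) * e1 + sin(phi) * e2))
      }
    } else {  # methane
      d <- 1 / sqrt(3)
      for (v in list(c(d, d, d), c(d, -d, -d), c(-d, d, -d), c(-d, -d, d))) {
        add_h(i, v)
      }
    }
  }
  atomic_config(elements, pos)
}

#' Generic bonded surrogate for any C/H molecule
#'
#' Assigns harmonic bonds and angles from perceived connectivity with
#' generic force-field-style parameters (C-C 600, C-H 680 kcal/mol/A^2;
#' angle constants 80-120 kcal/mol/rad^2). In locality mode (default) only
#' bonded terms are present, so no energy term couples atoms farther apart
#' than ~3.1 Angstrom -- fragmentation is then exact up to cap artifacts.
#' With \code{locality = FALSE}, 1-5+ Lennard-Jones interactions are added.
#' Used both by the built-in alkane system and to label arbitrary
#' hydrogen-capped fragments.
#'
#' @param config An \code{atomic_config} containing only C and H.
#' @param locality Bonded-only surrogate (TRUE) or add Lennard-Jones.
#' @param lj_eps,lj_sigma Lennard-Jones parameters.
#' @return A \code{surrogate_calculator}.
#' @export
alkane_like_surrogate <- function(config, locality = TRUE, lj_eps = 0.1,
                                  lj_sigma = 2.8) {
  if (!all(config$elements %in% c("C", "H"))) {
    stop("alkane_like_surrogate handles C/H molecules only")
  }
  bonds <- perceive_bonds(config)
  el <- config$elements
  bm <- bonds$bonds
  is_cc <- el[bm[, 1]] == "C" & el[bm[, 2]] == "C"
  bond_df <- data.frame(i = bm[, 1], j = bm[, 2], type = "harmonic",
                        k = ifelse(is_cc, 600, 680), D = NA, a = NA,
                        r0 = ifelse(is_cc, 1.526, 1.09))
  # angles: every bonded pair around a common vertex
  ang <- NULL
  for (j in seq_along(el)) {
    nb <- which(bonds$adjacency[j, ])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    typ <- paste0(el[cmb[1, ]], el[cmb[2, ]])
    ang <- rbind(ang, data.frame(
      i = cmb[1, ], j = j, k = cmb[2, ],
      ktheta = ifelse(el[j] == "C" & typ == "CC", 120,
               ifelse(typ %in% c("CH", "HC"), 100, 80)),
      theta0 = ifelse(typ == "CC", 112, ifelse(typ == "HH", 107.8, 109.5)) *
        pi / 180))
  }
  lj <- NULL
  if (!locality) {
    # LJ between atoms separated by more than three bonds
    sp <- .graph_distances(bonds$adjacency)
    cand <- which(upper.tri(sp) & sp > 3, arr.ind = TRUE)
    if (nrow(cand)) {
      lj <- data.frame(i = cand[, 1], j = cand[, 2], eps = lj_eps,
                       sigma = lj_sigma)
    }
  }
  surrogate_pes(el, bonds = bond_df, angles = ang, lj = lj,
                charges = rep(0, length(el)),
                lj_cutoff = 6.0,
                interaction_range = if (locality) 3.1 else 6.0)
}

.sys_alkane <- function(n = 8, locality = TRUE, lj_eps = 0.1,
                        lj_sigma = 2.8) {
  config <- .alkane_geometry(n)
  calc <- alkane_like_surrogate(config, locality = locality,
                                lj_eps = lj_eps, lj_sigma = lj_sigma)
  list(config = config, calculator = calc,
       bonds = perceive_bonds(config))
}

# BFS shortest path lengths over an adjacency matrix (small graphs).
.graph_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                   !is.finite(d[s, ]))
      d[s, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

.sys_proton_toy <- function(d_oo = 2.7, D_oh = 120, a_oh = 3.0,
                            r0_oh = 0.97) {
  # O - C - O skeleton plus a proton shared between the two oxygens
  elements <- c("O", "C", "O", "H")
  pos <- rbind(c(-d_oo / 2, 0, 0), c(0, 0.9, 0), c(d_oo / 2, 0, 0),
               c(-d_oo / 2 + r0_oh, 0, 0))
  r_co <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  calc <- surrogate_pes(
    elements,
    bonds = data.frame(
      i = c(1, 3, 1, 3),
      j = c(2, 2, 4, 4),
      type = c("harmonic", "harmonic", "morse", "morse"),
      k = c(700, 700, NA, NA),
      D = c(NA, NA, D_oh, D_oh),
      a = c(NA, NA, a_oh, a_oh),
      r0 = c(r_co, r_co, r0_oh, r0_oh)),
    angles = data.frame(i = 1, j = 2, k = 3, ktheta = 150,
                        theta0 = 2 * atan2(d_oo / 2, 0.9)),
    charges = c(-0.45, 0.9, -0.45, 1.0),
    interaction_range = 3.5)
  list(config = atomic_config(elements, pos), calculator = calc)
}

#' Proton-transfer double-well profile
#'
#' Energy of the shared proton along the O...O axis of the proton toy at
#' frozen heavy-atom geometry: the 1-D closed form
#' E(x) = morse(|x - x_O1|) + morse(|x - x_O2|) (plus the frozen skeleton
#' energy). Returns positions, energies and the barrier between the two
#' minima.
#'
#' @param system Output of \code{surrogate_system("proton_toy")}.
#' @param n_points Scan resolution.
#' @return List with \code{x}, \code{energy}, \code{barrier} (kcal/mol).
#' @export
proton_scan <- function(system, n_points = 401) {
  cfg <- system$config
  x1 <- cfg$positions[1, 1]; x2 <- cfg$positions[3, 1]
  xs <- seq(x1 + 0.4, x2 - 0.4, length.out = n_points)
  E <- vapply(xs, function(x) {
    c2 <- cfg
    c2$positions[4, ] <- c(x, 0, 0)
    calc_evaluate(system$calculator, c2, forces = FALSE)$energy
  }, 0)
  mid <- which.min(abs(xs - (x1 + x2) / 2))
  left_min <- min(E[seq_len(mid)]); right_min <- min(E[mid:length(E)])
  barrier <- E[mid] - max(left_min, right_min)
  list(x = xs, energy = E, barrier = barrier)
}

#' Generate a labeled dataset by surrogate molecular dynamics
#'
#' Runs seeded Langevin dynamics with the surrogate calculator and keeps
#' every \code{stride}-th frame, fully labeled (energy, forces, dipole, total
#' charge). Reproducible: the same seed yields the same dataset.
#'
#' @param calculator A \code{surrogate_calculator} (or any calculator usable
#'   by \code{\link{label_config}}).
#' @param start_config Starting \code{atomic_config}.
#' @param n Number of configurations to generate (>= 1).
#' @param temperature Sampling temperature (K); 500 K samples the
#'   spectroscopically relevant anharmonic region.
#' @param seed Integer seed.
#' @param stride MD steps between samples (decorrelation, default 40).
#' @param timestep Timestep in fs (default 0.5).
#' @return List of labeled \code{atomic_config}s.
#' @export
generate_dataset <- function(calculator, start_config, n, temperature = 500,
                             seed = 1L, stride = 40L, timestep = 0.5) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1L) return(list(label_config(calculator, start_config)))
  cfg <- md_config(timestep = timestep, temperature = temperature,
                   thermostat = "langevin", friction = 0.02,
                   n_steps = (n - 1L) * stride, equilibration_steps = 0L,
                   stride = stride, seed = seed)
  traj <- run_md(calculator, start_config, cfg)
  frames <- c(list(start_config$positions), traj$frames)[seq_len(n)]
  lapply(frames, function(p)
    label_config(calculator, atomic_config(start_config$elements, p)))
}
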