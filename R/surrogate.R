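# Analytic surrogate reference potentials: cheap, exact calculators producing
# energies, analytic forces, point-charge dipoles and total charges. They play
# the role of the electronic-structure reference at desk scale, so every
# pipeline stage (training, sampling, fragmentation, spectra) can be tested
# end to end. Terms: harmonic/Morse bonds, harmonic angles, cosine torsions,
# Lennard-Jones beyond three bonds; charges fixed or linearly geometry
# dependent (bond-increment model).

#' Create a surrogate reference potential
#'
#' @param elements Character vector of element symbols (length N).
#' @param bonds Data frame with columns \code{i, j, type} ("harmonic" or
#'   "morse"), \code{k} (kcal/mol/A^2, harmonic: E = 0.5 k (r - r0)^2),
#'   \code{D, a} (Morse: E = D (1 - exp(-a (r - r0)))^2 - D) and \code{r0}.
#' @param angles Optional data frame \code{i, j, k, ktheta, theta0}
#'   (j = vertex; E = 0.5 ktheta (theta - theta0)^2, theta0 in radians).
#' @param torsions Optional data frame \code{a, b, c, d, kphi, n, phi0}
#'   (E = kphi (1 + cos(n phi - phi0))).
#' @param lj Optional data frame \code{i, j, eps, sigma} of nonbonded pairs
#'   (truncated and shifted at \code{lj_cutoff}).
#' @param charges Numeric vector of per-atom charges q0 (e).
#' @param bond_increments Optional data frame \code{i, j, kq}: charge
#'   q_i gains kq (r_ij - r0_ij) and q_j loses it (geometry-dependent
#'   charges).
#' @param lj_cutoff Lennard-Jones cutoff (Angstrom).
#' @param interaction_range Declared locality radius (Angstrom): no energy
#'   term couples atoms farther apart than this. Used by fragmentation tests.
#' @return A \code{surrogate_calculator}.
#' @export
surrogate_pes <- function(elements, bonds, angles = NULL, torsions = NULL,
                          lj = NULL, charges = NULL, bond_increments = NULL,
                          lj_cutoff = 8.0, interaction_range = NA_real_) {
  if (is.null(charges)) charges <- rep(0, length(elements))
  structure(list(elements = as.character(elements), bonds = bonds,
                 angles = angles, torsions = torsions, lj = lj,
                 charges = charges, bond_increments = bond_increments,
                 lj_cutoff = lj_cutoff, interaction_range = interaction_range),
            class = "surrogate_calculator")
}

#' @export
print.surrogate_calculator <- function(x, ...) {
  cat("<surrogate_calculator>", length(x$elements), "atoms,",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bonds,",
      if (is.null(x$angles)) 0 else nrow(x$angles), "angles,",
      if (is.null(x$torsions)) 0 else nrow(x$torsions), "torsions\n")
  invisible(x)
}

# Angle (theta, gradients w.r.t. the three atoms); j is the vertex.
.angle_geometry <- function(pos, i, j, k) {
  u <- pos[i, ] - pos[j, ]; v <- pos[k, ] - pos[j, ]
  ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
  cost <- max(-1, min(1, sum(u * v) / (ru * rv)))
  dc_di <- v / (ru * rv) - cost * u / ru^2
  dc_dk <- u / (ru * rv) - cost * v / rv^2
  list(theta = acos(cost), cost = cost,
       dc_di = dc_di, dc_dk = dc_dk, dc_dj = -(dc_di + dc_dk))
}

# Dihedral angle and gradients (standard MD formulas).
.torsion_geometry <- function(pos, a, b, c, d) {
  b1 <- pos[b, ] - pos[a, ]; b2 <- pos[c, ] - pos[b, ]; b3 <- pos[d, ] - pos[c, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / nb2
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  ga <- nb2 / sum(n1^2) * n1
  gd <- -nb2 / sum(n2^2) * n2
  f1 <- sum(b1 * b2) / sum(b2^2)
  f2 <- sum(b3 * b2) / sum(b2^2)
  gb <- -(1 + f1) * ga + f2 * gd
  gc <- f1 * ga - (1 + f2) * gd
  list(phi = phi, ga = ga, gb = gb, gc = gc, gd = gd)
}

#' @export
calc_evaluate.surrogate_calculator <- function(calc, config, forces = TRUE,
                                               dipole = FALSE) {
  if (!identical(calc$elements, config$elements)) {
    stop("configuration does not match the surrogate topology ",
         "(element sequence differs)")
  }
  pos <- config$positions
  n <- nrow(pos)
  E <- 0
  F <- matrix(0, n, 3)
  addF <- function(idx, g) F[idx, ] <<- F[idx, ] - g  # g = dE/dR
  b <- calc$bonds
  if (!is.null(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      dv <- pos[j, ] - pos[i, ]
      d <- sqrt(sum(dv^2)); u <- dv / d
      if (identical(b$type[r], "morse")) {
        ex <- exp(-b$a[r] * (d - b$r0[r]))
        E <- E + b$D[r] * (1 - ex)^2 - b$D[r]
        dEdr <- 2 * b$D[r] * (1 - ex) * b$a[r] * ex
      } else {
        E <- E + 0.5 * b$k[r] * (d - b$r0[r])^2
        dEdr <- b$k[r] * (d - b$r0[r])
      }
      addF(j, dEdr * u); addF(i, -dEdr * u)
    }
  }
  if (!is.null(calc$angles)) {
    ang <- calc$angles
    for (r in seq_len(nrow(ang))) {
      g <- .angle_geometry(pos, ang$i[r], ang$j[r], ang$k[r])
      dth <- g$theta - ang$theta0[r]
      E <- E + 0.5 * ang$ktheta[r] * dth^2
      s <- sqrt(max(1 - g$cost^2, 1e-12))
      dEdc <- -ang$ktheta[r] * dth / s
      addF(ang$i[r], dEdc * g$dc_di)
      addF(ang$j[r], dEdc * g$dc_dj)
      addF(ang$k[r], dEdc * g$dc_dk)
    }
  }
  if (!is.null(calc$torsions)) {
    tor <- calc$torsions
    for (r in seq_len(nrow(tor))) {
      g <- .torsion_geometry(pos, tor$a[r], tor$b[r], tor$c[r], tor$d[r])
      arg <- tor$n[r] * g$phi - tor$phi0[r]
      E <- E + tor$kphi[r] * (1 + cos(arg))
      dEdphi <- -tor$kphi[r] * tor$n[r] * sin(arg)
      addF(tor$a[r], dEdphi * g$ga); addF(tor$b[r], dEdphi * g$gb)
      addF(tor$c[r], dEdphi * g$gc); addF(tor$d[r], dEdphi * g$gd)
    }
  }
  if (!is.null(calc$lj)) {
    lj <- calc$lj
    for (r in seq_len(nrow(lj))) {
      i <- lj$i[r]; j <- lj$j[r]
      dv <- pos[j, ] - pos[i, ]
      d <- sqrt(sum(dv^2))
      if (d >= calc$lj_cutoff) next
      s6 <- (lj$sigma[r] / d)^6
      sc6 <- (lj$sigma[r] / calc$lj_cutoff)^6
      E <- E + 4 * lj$eps[r] * (s6^2 - s6) - 4 * lj$eps[r] * (sc6^2 - sc6)
      dEdr <- 4 * lj$eps[r] * (-12 * s6^2 + 6 * s6) / d
      u <- dv / d
      addF(j, dEdr * u); addF(i, -dEdr * u)
    }
  }
  out <- list(energy = E)
  if (forces) out$forces <- F
  if (dipole) {
    q <- surrogate_charges(calc, config)
    com <- center_of_mass(config)
    rel <- sweep(pos, 2, com)
    out$dipole <- colSums(rel * q) * nnpir_constants$debye_per_eA
    out$total_charge <- sum(calc$charges)
    out$charges <- q
  }
  out
}

#' Atomic charges of a surrogate
#'
#' Fixed per-atom charges, optionally augmented by linear bond increments
#' (charge flowing along a bond in proportion to its stretch), giving a
#' smooth, geometry-dependent charge model whose total charge is conserved.
#'
#' @param calc A \code{surrogate_calculator}.
#' @param config An \code{atomic_config}.
#' @return Numeric vector of charges (e).
#' @export
surrogate_charges <- function(calc, config) {
  q <- calc$charges
  bi <- calc$bond_increments
  if (!is.null(bi)) {
    pos <- config$positions
    b <- calc$bonds
    for (r in seq_len(nrow(bi))) {
      i <- bi$i[r]; j <- bi$j[r]
      row <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))[1]
      d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      dq <- bi$kq[r] * (d - b$r0[row])
      q[i] <- q[i] + dq; q[j] <- q[j] - dq
    }
  }
  q
}
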