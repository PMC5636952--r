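# Atom-centered fragmentation with hydrogen capping: every atom of a large
# molecule becomes the center of one fragment containing all atoms within a
# cutoff radius. Severed single bonds to heavy atoms are capped by hydrogens
# placed along the original bond vector; if the free valency sits on a
# retained hydrogen, corresponds to a double bond, or two caps would overlap,
# the missing heavy atom is included instead and the rules re-applied.

#' Perceive bonds from geometry
#'
#' Two atoms are bonded when their distance is below
#' \code{tolerance * (r_cov_a + r_cov_b)} (Cordero covalent radii). A crude
#' bond-order guess marks bonds shorter than \code{double_frac} times the
#' radii sum as double bonds; explicit orders can be supplied downstream
#' instead.
#'
#' @param config An \code{atomic_config}.
#' @param tolerance Distance tolerance factor (default 1.2).
#' @param double_frac Fraction of the radii sum below which a bond between
#'   non-hydrogen atoms is classified as double (default 0.92).
#' @return A \code{bond_graph}: list with \code{adjacency} (N x N logical),
#'   \code{order} (N x N integer) and \code{bonds} (two-column index matrix).
#' @export
perceive_bonds <- function(config, tolerance = 1.2, double_frac = 0.92) {
  n <- n_atoms(config)
  radii <- .covalent_radii[config$elements]
  if (anyNA(radii)) {
    stop("no covalent radius for element(s): ",
         paste(unique(config$elements[is.na(radii)]), collapse = ", "))
  }
  dm <- distance_matrix(config$positions)
  thresh <- outer(radii, radii, `+`)
  adj <- dm < tolerance * thresh & upper.tri(dm)
  ord <- matrix(0L, n, n)
  ord[adj] <- 1L
  dbl <- adj & dm < double_frac * thresh &
    outer(config$elements != "H", config$elements != "H", `&`)
  ord[dbl] <- 2L
  adj <- adj | t(adj)
  ord <- ord + t(ord)
  # valence sanity check
  max_val <- c(H = 1, C = 4, N = 4, O = 2, F = 1, P = 5, S = 6, Cl = 1)
  val <- rowSums(adj)
  over <- which(val > max_val[config$elements])
  if (length(over)) {
    warning("hypervalent atom(s) at index: ", paste(over, collapse = ", "))
  }
  structure(list(adjacency = adj, order = ord,
                 bonds = which(upper.tri(adj) & adj, arr.ind = TRUE)),
            class = "bond_graph")
}

cap_bond_length <- function(element) {
  len <- .cap_bond_lengths[element]
  ifelse(is.na(len), 1.0, len)
}

#' Build one atom-centered fragment
#'
#' Retains every atom within \code{r_c} of the central atom, then resolves
#' severed bonds iteratively: a severed single bond from a retained heavy atom
#' is capped by a hydrogen along the original bond vector at the standard X-H
#' length; if the retained end is itself a hydrogen, or the severed bond is a
#' double bond, or two capping hydrogens would come closer than
#' \code{cap_overlap}, the missing heavy atom is included and the rules
#' re-applied. Retained coordinates are copied bitwise from the parent.
#'
#' @param config Parent \code{atomic_config}.
#' @param bonds A \code{bond_graph} for the parent.
#' @param central Index of the central atom.
#' @param r_c Cutoff radius in Angstrom (default 4.0, matching the descriptor
#'   cutoff).
#' @param cap_overlap Minimum allowed cap-cap distance (Angstrom).
#' @return A \code{fragment}: list with \code{geometry} (an
#'   \code{atomic_config} of members plus caps), \code{central_atom},
#'   \code{member_atoms} (parent indices), \code{caps} (data frame of cap
#'   positions and the parent bond each replaces).
#' @export
build_fragment <- function(config, bonds, central, r_c = 4.0,
                           cap_overlap = 0.9) {
  n <- n_atoms(config)
  if (central < 1 || central > n) stop("invalid central atom index")
  if (r_c <= 0) stop("cutoff must be positive")
  pos <- config$positions
  el <- config$elements
  d_central <- sqrt(colSums((t(pos) - pos[central, ])^2))
  members <- which(d_central <= r_c)
  if (length(members) == 1L) {
    warning("fragment of atom ", central, " contains only the central atom")
  }
  caps <- NULL
  repeat {
    inside <- logical(n); inside[members] <- TRUE
    # severed bonds: retained a -- removed b
    sev <- which(bonds$adjacency[members, , drop = FALSE] &
                 !matrix(inside, length(members), n, byrow = TRUE),
                 arr.ind = TRUE)
    a_idx <- members[sev[, 1]]
    b_idx <- sev[, 2]
    if (!length(a_idx)) break
    force_in <- unique(c(
      b_idx[el[a_idx] == "H"],                              # valency on an H
      b_idx[bonds$order[cbind(a_idx, b_idx)] >= 2L]         # double bond
    ))
    caps <- NULL
    if (length(force_in) == 0L) {
      # propose caps for all severed single bonds from heavy atoms
      cap_pos <- matrix(0, length(a_idx), 3)
      for (s in seq_along(a_idx)) {
        u <- pos[b_idx[s], ] - pos[a_idx[s], ]
        u <- u / sqrt(sum(u^2))
        cap_pos[s, ] <- pos[a_idx[s], ] + cap_bond_length(el[a_idx[s]]) * u
      }
      # overlapping caps force inclusion of both missing heavy atoms
      if (nrow(cap_pos) >= 2) {
        cd <- as.matrix(stats::dist(cap_pos))
        bad <- which(cd < cap_overlap & upper.tri(cd), arr.ind = TRUE)
        if (nrow(bad)) force_in <- unique(c(b_idx[bad[, 1]], b_idx[bad[, 2]]))
      }
      if (length(force_in) == 0L) {
        caps <- data.frame(x = cap_pos[, 1], y = cap_pos[, 2],
                           z = cap_pos[, 3],
                           bonded_to = a_idx, replaces = b_idx)
        break
      }
    }
    members <- sort(unique(c(members, force_in)))
  }
  if (is.null(caps)) {
    caps <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       bonded_to = integer(0), replaces = integer(0))
  }
  geom <- atomic_config(
    c(el[members], rep("H", nrow(caps))),
    rbind(pos[members, , drop = FALSE],
          as.matrix(caps[, c("x", "y", "z")])))
  structure(list(geometry = geom, central_atom = central,
                 member_atoms = members, caps = caps),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat("<fragment> center", x$central_atom, "|", length(x$member_atoms),
      "parent atoms +", nrow(x$caps), "caps\n")
  invisible(x)
}

#' Fragment a whole molecule
#'
#' One fragment per atom, deterministically.
#'
#' @inheritParams build_fragment
#' @return List of N \code{fragment} objects.
#' @export
fragment_molecule <- function(config, bonds, r_c = 4.0) {
  lapply(seq_len(n_atoms(config)), function(i)
    build_fragment(config, bonds, i, r_c))
}

# Sorted interatomic distance profile; cheap geometry hash for dedup.
.fragment_signature <- function(geom) {
  list(formula = sort(geom$elements),
       dists = sort(as.vector(stats::dist(geom$positions))))
}

#' Deduplicate equivalent fragments
#'
#' Two fragments are equivalent when they share the element multiset and
#' their sorted interatomic distance profiles agree within \code{tol}
#' (Angstrom). Keeps the first representative of each equivalence class.
#'
#' @param fragments List of \code{fragment}s.
#' @param tol Distance tolerance in Angstrom.
#' @return List of unique fragments (attribute \code{map} gives, for each
#'   input, the index of its representative in the output).
#' @export
deduplicate_fragments <- function(fragments, tol = 1e-3) {
  sigs <- lapply(fragments, function(f) .fragment_signature(f$geometry))
  keep <- integer(0)
  map <- integer(length(fragments))
  for (i in seq_along(fragments)) {
    found <- 0L
    for (kk in seq_along(keep)) {
      k <- keep[kk]
      if (length(sigs[[i]]$formula) == length(sigs[[k]]$formula) &&
          all(sigs[[i]]$formula == sigs[[k]]$formula) &&
          max(abs(sigs[[i]]$dists - sigs[[k]]$dists)) < tol) {
        found <- kk; break
      }
    }
    if (found == 0L) {
      keep <- c(keep, i)
      map[i] <- length(keep)
    } else {
      map[i] <- found
    }
  }
  out <- fragments[keep]
  attr(out, "map") <- map
  out
}
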