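# Level-set boundary walls: two planar walls at the lipid-head heights, two
# hemispherical outer walls capping the water droplets, and a membrane wall
# that follows the initial protein surface (soft-min distance field over the
# initial C-alpha positions, offset by r_p).

#' Construct a wall set from a structure
#'
#' Builds the five level-set walls around a membrane protein: a slab of
#' thickness `membrane_thickness` centered on the protein center of mass
#' (planar walls 1 and 2 at its faces), hemispheres (walls 3 and 4) centered
#' at the lipid-head heights on the protein vertical axis with radii chosen
#' so the minimum protein-atom-to-wall distance outside the slab equals
#' `water_margin`, and the membrane wall (wall 5)
#' `phi5(r) = r_p - softmin_j |r - c_j|` over the initial C-alpha positions.
#'
#' Walls 1-2 carry a purely repulsive inverse-sixth potential cut at
#' `d_rep`; walls 3-5 carry a softened Lennard-Jones potential whose minimum
#' sits exactly at `d = r_p` and which crosses zero at `d = sigma`, cut at
#' `1.5 * r_p`. Forces are shifted to vanish continuously at the cutoffs and
#' capped at `f_max`.
#'
#' @param structure an `mmcg_structure` with C-alpha atoms spanning the slab.
#' @param membrane_thickness slab thickness (nm).
#' @param water_margin minimum protein-to-outer-wall distance (nm).
#' @param r_p membrane-wall offset from the C-alpha field (nm).
#' @param beta soft-min smoothing scale (1/nm); larger is closer to the
#'   hard minimum.
#' @param eps well depth of the boundary potentials (kJ/mol).
#' @param sigma zero-crossing distance of the attractive walls and length
#'   scale of the repulsive walls (nm); must satisfy `sigma <= r_p * 2^(-1/6)`
#'   so the softened minimum can sit at `r_p`.
#' @param d_rep force cutoff of the repulsive planar walls (nm).
#' @param f_max force cap (kJ mol-1 nm-1).
#' @param aromatic_dist TRP/TYR side-chain atoms whose C-beta starts within
#'   this level-set distance of the membrane wall are wall-coupled (nm).
#' @return an object of class `mmcg_wallset`.
#' @export
build_walls <- function(structure, membrane_thickness = 3.1, water_margin = 2.0,
                        r_p = 0.2, beta = 50, eps = 1.0, sigma = 0.17,
                        d_rep = 0.7, f_max = 1000, aromatic_dist = 0.8) {
  a <- structure$atoms
  prot <- !a$is_water & !a$is_ligand
  if (!any(prot & a$name == "CA")) stop("structure has no C-alpha atoms")
  pxyz <- coords(structure)[prot, , drop = FALSE]
  m <- a$mass[prot]
  com <- unname(colSums(pxyz * m) / sum(m))
  z_lo <- com[3] - membrane_thickness / 2
  z_hi <- com[3] + membrane_thickness / 2
  up <- pxyz[, 3] > z_hi
  dn <- pxyz[, 3] < z_lo
  if (!any(up) || !any(dn))
    stop("no protein atoms outside the membrane slab; cannot construct hemispheres")
  chi3 <- c(com[1], com[2], z_hi)
  chi4 <- c(com[1], com[2], z_lo)
  r3 <- max(vnorm(sweep(pxyz[up, , drop = FALSE], 2, chi3))) + water_margin
  r4 <- max(vnorm(sweep(pxyz[dn, , drop = FALSE], 2, chi4))) + water_margin
  cj <- coords(structure)[prot & a$name == "CA", , drop = FALSE]
  ws <- .new_wallset(active = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                     z_lo = z_lo, z_hi = z_hi, chi3 = chi3, chi4 = chi4,
                     r3 = r3, r4 = r4, cj = cj, beta = beta, r_p = r_p,
                     eps = eps, sigma = sigma, d_rep = d_rep, f_max = f_max)
  ws$coupled <- wall_coupled_atoms(structure, ws, aromatic_dist = aromatic_dist)
  ws
}

#' Hemispherical droplet wall set
#'
#' A reduced wall set for stand-alone water droplets: one planar wall at
#' `z_plane` and one hemispherical cap of the given radius (walls 1+3 for an
#' upper droplet, 2+4 for a lower one). Potential parameters as in
#' [build_walls()].
#'
#' @param radius hemisphere radius (nm).
#' @param z_plane base-plane height (nm).
#' @param side `"upper"` or `"lower"`.
#' @param center xy center of the hemisphere.
#' @inheritParams build_walls
#' @return an `mmcg_wallset`.
#' @export
hemisphere_wallset <- function(radius, z_plane = 0, side = "upper",
                               center = c(0, 0), r_p = 0.2, beta = 50,
                               eps = 1.0, sigma = 0.17, d_rep = 0.7,
                               f_max = 1000) {
  stopifnot(radius > 0)
  upper <- side == "upper"
  .new_wallset(
    active = c(upper, !upper, upper, !upper, FALSE),
    z_lo = z_plane, z_hi = z_plane,
    chi3 = c(center, z_plane), chi4 = c(center, z_plane),
    r3 = radius, r4 = radius, cj = matrix(0, 0, 3), beta = beta, r_p = r_p,
    eps = eps, sigma = sigma, d_rep = d_rep, f_max = f_max)
}

#' @noRd
.new_wallset <- function(active, z_lo, z_hi, chi3, chi4, r3, r4, cj, beta,
                         r_p, eps, sigma, d_rep, f_max) {
  stopifnot(z_hi >= z_lo, r3 > 0, r4 > 0, r_p > 0, f_max > 0, beta > 0)
  smax <- r_p / 2^(1 / 6)
  if (sigma > smax + 1e-12)
    stop("sigma must be <= r_p * 2^(-1/6) = ", signif(smax, 4),
         " nm for the softened minimum to sit at r_p")
  delta <- (r_p - 2^(1 / 6) * sigma) / (2^(1 / 6) - 1)
  structure(list(
    active = as.logical(active), z_lo = z_lo, z_hi = z_hi,
    chi3 = as.numeric(chi3), chi4 = as.numeric(chi4), r3 = r3, r4 = r4,
    cj = cj, beta = beta, r_p = r_p, eps = eps, sigma = sigma,
    d_rep = d_rep, delta = delta, sigma_p = sigma + delta,
    cut345 = 1.5 * r_p, f_max = f_max, coupled = NULL
  ), class = "mmcg_wallset")
}

#' @export
print.mmcg_wallset <- function(x, ...) {
  cat("MM/CG wall set: active walls", paste(which(x$active), collapse = ","),
      "| slab z =", signif(x$z_lo, 4), "..", signif(x$z_hi, 4),
      "nm | r3 =", signif(x$r3, 4), "r4 =", signif(x$r4, 4),
      "nm | r_p =", x$r_p, "nm\n")
  invisible(x)
}

#' @noRd
.wall_cpp <- function(ws) {
  list(active = as.integer(ws$active), z_lo = ws$z_lo, z_hi = ws$z_hi,
       chi3 = ws$chi3, chi4 = ws$chi4, r3 = ws$r3, r4 = ws$r4,
       cj = ws$cj, beta = ws$beta, r_p = ws$r_p, eps = ws$eps,
       sigma = ws$sigma, d_rep = ws$d_rep, sigma_p = ws$sigma_p,
       delta = ws$delta, cut345 = ws$cut345, f_max = ws$f_max)
}

#' Wall-coupled atoms
#'
#' The atoms the boundary potentials act on, with their coupling mode: all
#' water atoms see the full gated wall set (mode 0); protein C-alpha atoms
#' (MM and CG alike) and side-chain atoms of TRP/TYR residues whose C-beta
#' starts within `aromatic_dist` (level-set value) of the membrane wall
#' couple to the membrane wall phi5 only (mode 1), so a protein atom
#' crossing the slab face never collides with the water-confinement walls.
#'
#' @param structure an `mmcg_structure`.
#' @param wallset an `mmcg_wallset`.
#' @param aromatic_dist coupling distance for membrane-facing aromatics (nm).
#' @return data frame with columns `atom` (index) and `mode` (0 = all walls,
#'   1 = membrane wall only).
#' @export
wall_coupled_atoms <- function(structure, wallset, aromatic_dist = 0.8) {
  a <- structure$atoms
  prot <- !a$is_water & !a$is_ligand
  wat <- which(a$is_water)
  memb <- which(prot & a$name == "CA")
  if (wallset$active[5] && nrow(wallset$cj) > 0) {
    aro <- which(prot & a$resname %in% c("TRP", "TYR") & a$name == "CB")
    if (length(aro) > 0) {
      phi5 <- cpp_phi(coords(structure)[aro, , drop = FALSE],
                      .wall_cpp(wallset), 5L)
      keep <- is.finite(phi5) & abs(phi5) <= aromatic_dist
      # side-chain atoms of the facing residues, restricted to atoms that
      # start inside the attractive zone of the membrane-wall potential
      # (sigma .. cutoff): atoms deeper than the zero crossing would start
      # against the repulsive core and be crushed rather than anchored
      key <- paste(a$chain[aro], a$resid[aro])[keep]
      side <- which(prot & a$name != "CA" &
                      paste(a$chain, a$resid) %in% key)
      if (length(side) > 0) {
        p5 <- .ungated_phi5(coords(structure)[side, , drop = FALSE], wallset)
        side <- side[p5 >= wallset$sigma & p5 <= wallset$cut345]
      }
      memb <- sort(unique(c(memb, side)))
    }
  }
  data.frame(atom = c(wat, memb),
             mode = rep(c(0L, 1L), c(length(wat), length(memb))))
}

# normalise a coupled-atom spec (data frame or plain index vector) to a
# list(idx0, mode) with 0-based indices for the C++ layer
#' @noRd
.coupled_cpp <- function(coupled) {
  if (is.data.frame(coupled))
    list(idx0 = as.integer(coupled$atom) - 1L, mode = as.integer(coupled$mode))
  else
    list(idx0 = as.integer(coupled) - 1L,
         mode = integer(length(coupled)))
}

#' Level-set wall distance
#'
#' Returns `d = min_i phi_i(point)` over the walls applicable at each point
#' and the index of the arg-min wall (ties broken by lowest index). Positive
#' `d` marks the allowed region.
#'
#' @param points `n x 3` matrix (nm) or a length-3 vector.
#' @param wallset an `mmcg_wallset`.
#' @return data frame with columns `d` (nm) and `wall` (1-5).
#' @export
wall_distance <- function(points, wallset) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  res <- cpp_wall_distance(points, .wall_cpp(wallset))
  data.frame(d = res$d, wall = res$wall)
}

#' Level-set value of one wall
#'
#' Gated evaluation of a single `phi_i`; returns `Inf` where the wall is
#' inactive or not applicable (wrong side of the slab).
#'
#' @param points `n x 3` matrix (nm).
#' @param wallset an `mmcg_wallset`.
#' @param which wall index 1-5.
#' @return numeric vector of level-set values (nm).
#' @export
wall_phi <- function(points, wallset, which) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  cpp_phi(points, .wall_cpp(wallset), as.integer(which))
}

#' Boundary potential
#'
#' The energy-shifted wall potential as a function of the level-set
#' distance: walls 1-2 are purely repulsive (`eps * (sigma/d)^6`, shifted to
#' zero at `d_rep`); walls 3-5 are a softened Lennard-Jones
#' `4 eps ((sigma'/(d+Delta))^12 - (sigma'/(d+Delta))^6)` re-parameterised so
#' the minimum sits exactly at `d = r_p` and the unshifted potential crosses
#' zero at `d = sigma`, shifted to zero at the `1.5 * r_p` cutoff. At
#' non-positive `d` the potential is evaluated at a small floor distance;
#' confinement there is enforced by the capped force, not the potential.
#'
#' @param d level-set distance(s) (nm).
#' @param wall_index wall index 1-5 (scalar or vector).
#' @param wallset an `mmcg_wallset`.
#' @return energies (kJ/mol).
#' @export
wall_potential <- function(d, wall_index, wallset) {
  wi <- as.integer(rep_len(wall_index, length(d)))
  cpp_wall_potential(as.numeric(d), wi, .wall_cpp(wallset))
}

#' Scalar wall force
#'
#' The shifted, capped force magnitude `-dV/dd` as a function of level-set
#' distance: shifted so it vanishes continuously at the wall cutoff and
#' clamped to `f_max` (exactly `f_max` at and below the wall). Positive
#' values push toward the allowed region.
#'
#' @inheritParams wall_potential
#' @return forces (kJ mol-1 nm-1).
#' @export
wall_force_profile <- function(d, wall_index, wallset) {
  wi <- as.integer(rep_len(wall_index, length(d)))
  cpp_wall_force_scalar(as.numeric(d), wi, .wall_cpp(wallset))
}

#' Wall forces on coupled atoms
#'
#' Evaluates the boundary potential energy and the force on every
#' wall-coupled atom (direction along the inward level-set gradient).
#' The returned energy is the exact antiderivative of the applied shifted,
#' capped force (linear inside the cap region), so that total energy is
#' conserved in dynamics; the energy-shifted potential profile reported by
#' [wall_potential()] differs from it by the force-shift term.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param wallset an `mmcg_wallset`.
#' @param coupled wall-coupled atoms: a data frame from
#'   [wall_coupled_atoms()] or a plain index vector (treated as mode 0);
#'   defaults to the wall set's own coupling list.
#' @return list with `energy` (kJ/mol) and `forces` (`n x 3`).
#' @export
wall_forces <- function(positions, wallset, coupled = NULL) {
  coupled <- coupled %||% wallset$coupled
  if (is.null(coupled)) stop("wall set has no coupled-atom list; pass `coupled`")
  cc <- .coupled_cpp(coupled)
  cpp_wall_energy_forces(positions, .wall_cpp(wallset), cc$idx0, cc$mode)
}

#' Smoothed minimum
#'
#' Overflow-safe log-sum-exp soft minimum
#' `-(1/beta) log sum_j exp(-beta d_j)`; converges to the hard minimum as
#' `beta` grows and is infinitely differentiable in the inputs.
#'
#' @param d numeric vector of distances (nm).
#' @param beta smoothing scale (1/nm), > 0.
#' @return the smoothed minimum (nm).
#' @export
smooth_min <- function(d, beta) {
  stopifnot(length(d) >= 1, beta > 0)
  cpp_softmin(as.numeric(d), beta)
}

# membrane-wall level set r_p - softmin without the slab gating, used for
# membrane-anchored (mode 1) atoms and their selection
#' @noRd
.ungated_phi5 <- function(points, wallset) {
  cj <- wallset$cj
  vapply(seq_len(nrow(points)), function(k) {
    d <- sqrt((cj[, 1] - points[k, 1])^2 + (cj[, 2] - points[k, 2])^2 +
                (cj[, 3] - points[k, 3])^2)
    wallset$r_p - smooth_min(d, wallset$beta)
  }, numeric(1))
}
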