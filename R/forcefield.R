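# Energy terms of the hybrid potential and their analytic forces. The total
# potential splits into E_MM + E_I + E_MM/I (atomistic), E_CG (Go model),
# E_CG/I (coupling) and E_wall (boundary potentials); the stochastic solvent
# term is realised in the integrator as Langevin friction + noise, not as a
# potential.

#' Go-model bonded energy
#'
#' Harmonic interaction between consecutive CG beads,
#' `sum (K_b/2) (r_ij - b_ij)^2`. Zero exactly at the native distances.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param pairs data frame with columns `i`, `j` (atom indices), `k_b`
#'   (kJ/mol/nm^2) and `b0` (nm), e.g. `topology$go_bonds`.
#' @return list with `energy` (kJ/mol) and `forces` (`n x 3`,
#'   kJ mol-1 nm-1, the analytic negative gradient).
#' @export
go_bonded_energy <- function(positions, pairs) {
  pm <- .pairs_mat(pairs)
  cpp_go_bonded(positions, pm, as.numeric(pairs$k_b), as.numeric(pairs$b0))
}

#' Go-model Morse contact energy
#'
#' Morse-type native contacts
#' `V(r) = V0 ((1 - e^{-B_ij (r - b_ij)})^2 - 1)`: the minimum is `-V0` at
#' the native distance `b_ij` and the dissociated limit is zero, so the well
#' depth equals `V0`.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param contacts data frame with columns `i`, `j`, `b0` (nm), `B` (1/nm),
#'   `v0` (kJ/mol), e.g. `topology$go_contacts`.
#' @return list with `energy` and `forces`.
#' @export
go_morse_energy <- function(positions, contacts) {
  pm <- .pairs_mat(contacts)
  cpp_go_morse(positions, pm, as.numeric(contacts$b0),
               as.numeric(contacts$B), as.numeric(contacts$v0))
}

#' CG/interface coupling energy
#'
#' The CG-interface coupling uses the same functional forms as the CG
#' region: harmonic bonds between CG beads and sequence-adjacent interface
#' C-alphas, Morse contacts between CG beads and interface C-alpha/C-beta
#' atoms.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param topology an `mmcg_topology`.
#' @return list with `energy`, `bonded`, `morse` and `forces`.
#' @export
coupling_energy <- function(positions, topology) {
  b <- go_bonded_energy(positions, topology$cpl_bonds)
  m <- go_morse_energy(positions, topology$cpl_contacts)
  list(energy = b$energy + m$energy, bonded = b$energy, morse = m$energy,
       forces = b$forces + m$forces)
}

#' Atomistic (MM-region) energy
#'
#' Harmonic bonds and angles, periodic dihedrals, and LJ 12-6 + Coulomb
#' nonbonded terms with a plain cutoff, energy-shifted to be continuous at
#' the cutoff. The nonbonded sum runs over all atomistic atom pairs within
#' the cutoff, excluding bonded 1-2 and angle 1-3 pairs; this call builds
#' the exact pair list afresh (no neighbour-list skin), so it also serves as
#' the brute-force reference for the dynamics engine.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param topology an `mmcg_topology`.
#' @param cutoff nonbonded cutoff (nm); 1.6 nm by default.
#' @param pbc,box optional periodic minimum-image treatment of nonbonded
#'   distances (box lengths in nm).
#' @return list with `energy`, the split `e_mm`/`e_i`/`e_mmi` (terms wholly
#'   in the MM region, wholly in the interface, or mixed) and `forces`.
#' @export
mm_energy <- function(positions, topology, cutoff = 1.6, pbc = FALSE,
                      box = NULL) {
  tc <- .topo_cpp(topology, cutoff = cutoff, pbc = pbc, box = box)
  pairs <- cpp_build_pairs(positions, tc$atomistic_idx, cutoff, tc$excl_i,
                           tc$excl_j, tc$pbc, tc$box)
  nb <- cpp_nonbonded(positions, pairs, tc$sigma, tc$eps, tc$q, cutoff,
                      tc$group, tc$pbc, tc$box)
  bd <- cpp_mm_bonded(positions, tc$bnd_p, tc$bnd_k, tc$bnd_r, tc$ang_t,
                      tc$ang_k, tc$ang_th, tc$dih_q, tc$dih_k, tc$dih_n,
                      tc$dih_ph, tc$group)
  e_mm <- nb$e_mm + bd$e_mm
  e_i <- nb$e_i + bd$e_i
  e_mmi <- nb$e_mmi + bd$e_mmi
  list(energy = e_mm + e_i + e_mmi, e_mm = e_mm, e_i = e_i, e_mmi = e_mmi,
       forces = nb$forces + bd$forces)
}

#' Total hybrid energy and forces
#'
#' Evaluates every term of the hybrid potential and returns a per-term
#' energy report together with the total force matrix.
#'
#' @param positions `n x 3` coordinate matrix (nm).
#' @param topology an `mmcg_topology`.
#' @param wallset an `mmcg_wallset` or `NULL` (no boundary potentials).
#' @param cutoff nonbonded cutoff (nm).
#' @param pbc,box optional periodic minimum image for nonbonded terms.
#' @return list with `report` (an `mmcg_energy`) and `forces`.
#' @export
total_energy <- function(positions, topology, wallset = NULL, cutoff = 1.6,
                         pbc = FALSE, box = NULL) {
  tc <- .topo_cpp(topology, cutoff = cutoff, pbc = pbc, box = box)
  wl <- NULL
  if (!is.null(wallset)) {
    coupled <- wallset$coupled
    if (is.null(coupled))
      stop("wall set has no coupled-atom list; use wall_coupled_atoms()")
    cc <- .coupled_cpp(coupled)
    tc$wall_idx <- cc$idx0
    tc$wall_mode <- cc$mode
    wl <- .wall_cpp(wallset)
  }
  pairs <- cpp_build_pairs(positions, tc$atomistic_idx, cutoff, tc$excl_i,
                           tc$excl_j, tc$pbc, tc$box)
  res <- cpp_eval_all(positions, tc, wl, pairs)
  e <- res$energies
  report <- structure(list(
    E_MM = e[["e_mm"]], E_I = e[["e_i"]], E_MM_I = e[["e_mmi"]],
    E_CG = e[["e_cg"]], E_CG_I = e[["e_cgi"]], E_wall = e[["e_wall"]],
    total = e[["e_pot"]]), class = "mmcg_energy")
  list(report = report, forces = res$forces)
}

#' @export
print.mmcg_energy <- function(x, ...) {
  cat(sprintf(
    "Potential energy (kJ/mol): total %.4f\n  E_MM %.4f | E_I %.4f | E_MM/I %.4f | E_CG %.4f | E_CG/I %.4f | E_wall %.4f\n",
    x$total, x$E_MM, x$E_I, x$E_MM_I, x$E_CG, x$E_CG_I, x$E_wall))
  invisible(x)
}

#' @noRd
.pairs_mat <- function(df) {
  m <- as.matrix(df[, c("i", "j"), drop = FALSE])
  storage.mode(m) <- "integer"
  m - 1L
}
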