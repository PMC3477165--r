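# Hybrid topology construction: Go-model bonded and Morse contact terms for
# the CG region, Go-type coupling between CG beads and interface C-alpha /
# C-beta atoms, MM bonded and nonbonded terms for the atomistic subsystem,
# and SHAKE constraints for hydrogen-containing bonds.

#' Build the hybrid MM/CG topology
#'
#' Instantiates every interaction term of the scheme:
#' \itemize{
#'   \item a harmonic Go bond for each pair of sequence-consecutive CG beads,
#'     with equilibrium `b_ij` equal to the native distance;
#'   \item a Morse-type contact `V(r) = V0 ((1 - e^{-B_ij (r - b_ij)})^2 - 1)`
#'     for every non-consecutive CG bead pair with native distance below
#'     `native_contact_cutoff`, with `B_ij = B_const + 6 / b_ij` (1/nm) —
#'     `B_const = 5` for membrane proteins, `0` for soluble ones;
#'   \item coupling terms between the CG and interface regions of the same
#'     functional forms: harmonic bonds to sequence-adjacent interface
#'     C-alphas and Morse contacts to interface C-alpha and C-beta atoms
#'     within the contact cutoff;
#'   \item MM bonded (harmonic bonds/angles, periodic dihedrals) and
#'     nonbonded (LJ 12-6 + Coulomb) terms for the atomistic atoms
#'     (MM + I residues, waters, ligand) from the parameter table, including
#'     a pseudo-backbone bond between consecutive atomistic protein residues;
#'   \item SHAKE distance constraints for every bond involving hydrogen.
#' }
#'
#' @param structure an `mmcg_structure`.
#' @param regions an `mmcg_regions` from [assign_regions()], or `NULL` for a
#'   system without protein (everything atomistic).
#' @param go_params list with `K_b` (kJ/mol/nm^2), `V_0` (kJ/mol, well
#'   depth), `B_const` (1/nm).
#' @param native_contact_cutoff native-distance cutoff for Morse contacts (nm).
#' @param mm_params an `mmcg_params` table ([read_mm_params()]); defaults to
#'   the built-in toy set.
#' @return an object of class `mmcg_topology`.
#' @export
build_hybrid_topology <- function(structure, regions = NULL,
                                  go_params = list(K_b = 1000, V_0 = 5.3,
                                                   B_const = 5),
                                  native_contact_cutoff = 1.2,
                                  mm_params = NULL) {
  mm_params <- mm_params %||% default_mm_params()
  regions <- regions %||% .trivial_regions(structure)
  a <- structure$atoms
  xyz <- coords(structure)
  n <- nrow(a)
  K_b <- go_params$K_b %||% 1000
  V_0 <- go_params$V_0 %||% 5.3
  B_const <- go_params$B_const %||% 5
  lab <- regions$atom_label

  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # ---- CG Go model -------------------------------------------------------
  beads <- regions$cg_beads
  bead_chain <- a$chain[beads]
  bead_resid <- a$resid[beads]
  go_bonds <- .empty_pairs(c("i", "j", "k_b", "b0"))
  go_contacts <- .empty_pairs(c("i", "j", "b0", "B", "v0"))
  if (length(beads) > 1) {
    ord <- order(bead_chain, bead_resid)
    beads <- beads[ord]; bead_chain <- bead_chain[ord]; bead_resid <- bead_resid[ord]
    bonded_key <- character(0)
    gb <- list()
    for (k in seq_len(length(beads) - 1)) {
      if (bead_chain[k] == bead_chain[k + 1] &&
          bead_resid[k + 1] - bead_resid[k] == 1L) {
        b0 <- dist_ij(beads[k], beads[k + 1])
        if (b0 <= 0) stop("zero native distance between consecutive CG beads ",
                          beads[k], " and ", beads[k + 1])
        gb[[length(gb) + 1L]] <- c(beads[k], beads[k + 1], K_b, b0)
        bonded_key <- c(bonded_key, paste(beads[k], beads[k + 1]))
      }
    }
    if (length(gb) > 0) {
      go_bonds <- as.data.frame(do.call(rbind, gb))
      names(go_bonds) <- c("i", "j", "k_b", "b0")
    }
    bxyz <- xyz[beads, , drop = FALSE]
    gc <- list()
    for (p in seq_len(length(beads) - 1)) {
      dp <- vnorm(sweep(bxyz[(p + 1):length(beads), , drop = FALSE], 2, bxyz[p, ]))
      for (qq in which(dp < native_contact_cutoff)) {
        q <- p + qq
        adjacent <- bead_chain[p] == bead_chain[q] &&
          abs(bead_resid[q] - bead_resid[p]) == 1L
        if (adjacent) next
        b0 <- dp[qq]
        if (b0 <= 0) stop("zero native distance between CG beads ", beads[p],
                          " and ", beads[q], " (clashing input)")
        gc[[length(gc) + 1L]] <- c(beads[p], beads[q], b0, B_const + 6 / b0, V_0)
      }
    }
    if (length(gc) > 0) {
      go_contacts <- as.data.frame(do.call(rbind, gc))
      names(go_contacts) <- c("i", "j", "b0", "B", "v0")
    }
  }

  # ---- CG / I coupling ---------------------------------------------------
  cpl_bonds <- .empty_pairs(c("i", "j", "k_b", "b0"))
  cpl_contacts <- .empty_pairs(c("i", "j", "b0", "B", "v0"))
  i_ca <- regions$interface_ca
  if (length(beads) > 0 && length(i_ca) > 0) {
    cb <- list()
    for (bi in seq_along(beads)) {
      adj <- i_ca[a$chain[i_ca] == bead_chain[bi] &
                    abs(a$resid[i_ca] - bead_resid[bi]) == 1L]
      for (j in adj) {
        b0 <- dist_ij(beads[bi], j)
        if (b0 <= 0) stop("zero native distance in CG/I bonded pair")
        cb[[length(cb) + 1L]] <- c(beads[bi], j, K_b, b0)
      }
    }
    if (length(cb) > 0) {
      cpl_bonds <- as.data.frame(do.call(rbind, cb))
      names(cpl_bonds) <- c("i", "j", "k_b", "b0")
    }
    itargets <- c(i_ca, regions$interface_cb)
    cc <- list()
    for (bi in seq_along(beads)) {
      d <- vnorm(sweep(xyz[itargets, , drop = FALSE], 2, xyz[beads[bi], ]))
      for (k in which(d < native_contact_cutoff)) {
        j <- itargets[k]
        # skip pairs already carried by a coupling bond
        if (a$name[j] == "CA" && a$chain[j] == bead_chain[bi] &&
            abs(a$resid[j] - bead_resid[bi]) == 1L) next
        b0 <- d[k]
        if (b0 <= 0) stop("zero native distance in CG/I contact pair")
        cc[[length(cc) + 1L]] <- c(beads[bi], j, b0, B_const + 6 / b0, V_0)
      }
    }
    if (length(cc) > 0) {
      cpl_contacts <- as.data.frame(do.call(rbind, cc))
      names(cpl_contacts) <- c("i", "j", "b0", "B", "v0")
    }
  }

  # ---- atomistic terms ---------------------------------------------------
  atomistic <- lab %in% c("MM", "I", "WATER", "LIGAND")
  prot <- !a$is_water & !a$is_ligand
  types <- rep(NA_character_, n)
  tm <- mm_params$typemap
  for (i in which(atomistic)) {
    hit <- which(tm$resname == a$resname[i] & tm$atomname == a$name[i])
    if (length(hit) == 0 && prot[i])
      hit <- which(tm$resname == "*" & tm$atomname == a$name[i])
    if (length(hit) == 0)
      stop("no parameter mapping for atom '", a$name[i], "' in residue ",
           a$resname[i], " ", a$resid[i])
    types[i] <- tm$type[hit[1]]
  }
  pa <- mm_params$atoms
  tix <- match(types, pa$type)
  if (any(atomistic & is.na(tix))) {
    bad <- unique(types[atomistic & is.na(tix)])
    stop("atom type(s) missing from ATOM records: ", paste(bad, collapse = ", "))
  }
  sigma <- ifelse(atomistic, pa$sigma[tix], 0)
  eps <- ifelse(atomistic, pa$eps[tix], 0)
  q <- ifelse(atomistic, pa$charge[tix], 0)
  sigma[is.na(sigma)] <- 0; eps[is.na(eps)] <- 0; q[is.na(q)] <- 0

  # intra-residue bonded records
  res_groups <- split(seq_len(n)[atomistic], paste(a$chain, a$resid)[atomistic])
  find_named <- function(idx, nm) idx[match(nm, a$name[idx])]
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (idx in res_groups) {
    rn <- a$resname[idx[1]]
    pick <- function(df) {
      if (is.null(df)) return(data.frame())
      rbind(df[df$resname == rn, , drop = FALSE],
            if (prot[idx[1]]) df[df$resname == "*", , drop = FALSE])
    }
    for (r in seq_len(nrow(pick(mm_params$bonds)))) {
      rec <- pick(mm_params$bonds)[r, ]
      ii <- find_named(idx, c(rec$n1, rec$n2))
      if (any(is.na(ii))) {
        if (rec$resname == "*") next
        stop("bond record ", rec$n1, "-", rec$n2, " has no matching atoms in ",
             rn, " ", a$resid[idx[1]])
      }
      bonds[[length(bonds) + 1L]] <- c(ii, rec$k, rec$r0)
    }
    for (r in seq_len(nrow(pick(mm_params$angles)))) {
      rec <- pick(mm_params$angles)[r, ]
      ii <- find_named(idx, c(rec$n1, rec$n2, rec$n3))
      if (any(is.na(ii))) {
        if (rec$resname == "*") next
        stop("angle record has no matching atoms in ", rn)
      }
      angles[[length(angles) + 1L]] <- c(ii, rec$k, rec$theta0 * pi / 180)
    }
    for (r in seq_len(nrow(pick(mm_params$dihedrals)))) {
      rec <- pick(mm_params$dihedrals)[r, ]
      ii <- find_named(idx, c(rec$n1, rec$n2, rec$n3, rec$n4))
      if (any(is.na(ii))) {
        if (rec$resname == "*") next
        stop("dihedral record has no matching atoms in ", rn)
      }
      dihedrals[[length(dihedrals) + 1L]] <- c(ii, rec$k, rec$mult,
                                               rec$phase * pi / 180)
    }
  }
  # pseudo-backbone between consecutive atomistic protein residues
  if (!is.null(mm_params$backbone)) {
    ap <- which(atomistic & prot & a$name == mm_params$backbone$n1[1])
    if (length(ap) > 1) {
      ord <- order(a$chain[ap], a$resid[ap])
      ap <- ap[ord]
      for (k in seq_len(length(ap) - 1)) {
        if (a$chain[ap[k]] == a$chain[ap[k + 1]] &&
            a$resid[ap[k + 1]] - a$resid[ap[k]] == 1L) {
          bb <- mm_params$backbone[1, ]
          bonds[[length(bonds) + 1L]] <- c(ap[k], ap[k + 1], bb$k, bb$r0)
        }
      }
    }
  }
  bonds_df <- if (length(bonds) > 0) {
    d <- as.data.frame(do.call(rbind, bonds)); names(d) <- c("i", "j", "k", "r0"); d
  } else .empty_pairs(c("i", "j", "k", "r0"))
  angles_df <- if (length(angles) > 0) {
    d <- as.data.frame(do.call(rbind, angles))
    names(d) <- c("i", "j", "k", "k_theta", "theta0"); d
  } else .empty_pairs(c("i", "j", "k", "k_theta", "theta0"))
  dihedrals_df <- if (length(dihedrals) > 0) {
    d <- as.data.frame(do.call(rbind, dihedrals))
    names(d) <- c("i", "j", "k", "l", "k_phi", "mult", "phase"); d
  } else .empty_pairs(c("i", "j", "k", "l", "k_phi", "mult", "phase"))

  # SHAKE constraints: every bond involving hydrogen
  hyd <- a$element == "H"
  ch <- bonds_df$i > 0 & (hyd[bonds_df$i] | hyd[bonds_df$j])
  constraints <- if (any(ch)) {
    data.frame(i = bonds_df$i[ch], j = bonds_df$j[ch], d = bonds_df$r0[ch])
  } else .empty_pairs(c("i", "j", "d"))

  # exclusions: bonded 1-2 pairs, angle 1-3 pairs, constraint pairs
  ex <- rbind(as.matrix(bonds_df[, c("i", "j")]),
              as.matrix(angles_df[, c("i", "k")]))
  ex <- if (nrow(ex) > 0) unique(t(apply(ex, 1, sort))) else
    matrix(integer(0), 0, 2)

  # per-atom region group for the energy decomposition:
  # 0 = MM-region/water/ligand, 1 = interface, -1 = CG bead
  group <- ifelse(lab == "I", 1L, ifelse(lab == "CG", -1L, 0L))

  topo <- structure(list(
    n_atoms = n,
    mass = a$mass,
    go_bonds = go_bonds, go_contacts = go_contacts,
    cpl_bonds = cpl_bonds, cpl_contacts = cpl_contacts,
    bonds = bonds_df, angles = angles_df, dihedrals = dihedrals_df,
    sigma = sigma, eps = eps, charge = q,
    atomistic = atomistic, group = group,
    exclusions = ex, constraints = constraints,
    cg_beads = beads, regions = regions,
    go_params = list(K_b = K_b, V_0 = V_0, B_const = B_const),
    native_contact_cutoff = native_contact_cutoff
  ), class = "mmcg_topology")
  topo
}

#' @noRd
.empty_pairs <- function(cols) {
  d <- as.data.frame(matrix(numeric(0), 0, length(cols)))
  names(d) <- cols
  d
}

#' @export
print.mmcg_topology <- function(x, ...) {
  cat("MM/CG topology:", x$n_atoms, "atoms |",
      nrow(x$go_bonds), "Go bonds,", nrow(x$go_contacts), "Morse contacts |",
      nrow(x$cpl_bonds), "+", nrow(x$cpl_contacts), "coupling terms |",
      nrow(x$bonds), "MM bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals |", nrow(x$constraints), "constraints\n")
  invisible(x)
}

# flatten a topology into the plain list the C++ kernels expect (0-based)
#' @noRd
.topo_cpp <- function(topo, cutoff = 1.6, pbc = FALSE, box = NULL) {
  pm <- function(df, cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    m - 1L
  }
  list(
    gob_p = pm(topo$go_bonds, c("i", "j")),
    gob_k = as.numeric(topo$go_bonds$k_b), gob_b = as.numeric(topo$go_bonds$b0),
    gom_p = pm(topo$go_contacts, c("i", "j")),
    gom_b = as.numeric(topo$go_contacts$b0),
    gom_B = as.numeric(topo$go_contacts$B),
    gom_v = as.numeric(topo$go_contacts$v0),
    cgb_p = pm(topo$cpl_bonds, c("i", "j")),
    cgb_k = as.numeric(topo$cpl_bonds$k_b), cgb_b = as.numeric(topo$cpl_bonds$b0),
    cgm_p = pm(topo$cpl_contacts, c("i", "j")),
    cgm_b = as.numeric(topo$cpl_contacts$b0),
    cgm_B = as.numeric(topo$cpl_contacts$B),
    cgm_v = as.numeric(topo$cpl_contacts$v0),
    bnd_p = pm(topo$bonds, c("i", "j")),
    bnd_k = as.numeric(topo$bonds$k), bnd_r = as.numeric(topo$bonds$r0),
    ang_t = pm(topo$angles, c("i", "j", "k")),
    ang_k = as.numeric(topo$angles$k_theta),
    ang_th = as.numeric(topo$angles$theta0),
    dih_q = pm(topo$dihedrals, c("i", "j", "k", "l")),
    dih_k = as.numeric(topo$dihedrals$k_phi),
    dih_n = as.integer(topo$dihedrals$mult),
    dih_ph = as.numeric(topo$dihedrals$phase),
    sigma = topo$sigma, eps = topo$eps, q = topo$charge, mass = topo$mass,
    group = as.integer(topo$group),
    atomistic_idx = which(topo$atomistic) - 1L,
    excl_i = as.integer(topo$exclusions[, 1]) - 1L,
    excl_j = as.integer(topo$exclusions[, 2]) - 1L,
    cons_p = pm(topo$constraints, c("i", "j")),
    cons_d = as.numeric(topo$constraints$d),
    wall_idx = integer(0),
    wall_mode = integer(0),
    cutoff = cutoff,
    pbc = pbc,
    box = if (is.null(box)) c(0, 0, 0) else as.numeric(box)
  )
}
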