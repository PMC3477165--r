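# MM / I / CG region assignment. Granularity is the residue: a residue is MM
# if any of its atoms is within mm_cutoff of the ligand, otherwise I if any
# atom is within interface_cutoff of an MM-residue atom, otherwise CG.
# Waters and the ligand are labelled separately and treated atomistically
# with the MM region.

#' Assign MM / I / CG regions
#'
#' @param structure an `mmcg_structure`.
#' @param ligand_selection atoms defining the binding ligand: a selection
#'   understood by [select_atoms()]; defaults to the structure's ligand flag.
#' @param mm_cutoff residue-to-ligand distance below which a residue is MM
#'   (nm; atom-to-atom minimum).
#' @param interface_cutoff distance from the MM boundary below which a
#'   residue is interface (nm; atom-to-atom minimum to MM-residue atoms).
#' @return an object of class `mmcg_regions`: per-atom labels
#'   (`MM`, `I`, `CG`, `WATER`, `LIGAND`), per-residue labels, CG bead atom
#'   indices, and interface C-alpha/C-beta indices.
#' @export
assign_regions <- function(structure, ligand_selection = "ligand",
                           mm_cutoff = 0.5, interface_cutoff = 0.6) {
  a <- structure$atoms
  lig <- select_atoms(structure, ligand_selection)
  if (length(lig) == 0) stop("empty ligand selection")
  xyz <- coords(structure)
  prot <- !a$is_water & !a$is_ligand
  rkey <- paste(a$chain, a$resid)
  pres <- unique(rkey[prot])

  # residue -> min distance to any ligand atom
  lxyz <- xyz[lig, , drop = FALSE]
  mindist_to <- function(idx, ref) {
    # min pairwise distance between two coordinate sets
    min(vapply(seq_len(nrow(ref)), function(k)
      min(vnorm(sweep(xyz[idx, , drop = FALSE], 2, ref[k, ]))), numeric(1)))
  }
  res_atoms <- split(which(prot), rkey[prot])[pres]
  dlig <- vapply(res_atoms, mindist_to, numeric(1), ref = lxyz)
  mm_res <- pres[dlig < mm_cutoff]
  if (length(mm_res) == 0)
    warning("no residue within ", mm_cutoff,
            " nm of the ligand; MM region is ligand + waters only")

  other <- setdiff(pres, mm_res)
  if (length(mm_res) > 0 && length(other) > 0) {
    mmxyz <- xyz[unlist(res_atoms[mm_res]), , drop = FALSE]
    dmm <- vapply(res_atoms[other], mindist_to, numeric(1), ref = mmxyz)
    i_res <- other[dmm < interface_cutoff]
  } else {
    i_res <- character(0)
  }
  cg_res <- setdiff(other, i_res)

  res_label <- setNames(rep("CG", length(pres)), pres)
  res_label[mm_res] <- "MM"
  res_label[i_res] <- "I"

  atom_label <- rep(NA_character_, nrow(a))
  atom_label[a$is_water] <- "WATER"
  atom_label[a$is_ligand] <- "LIGAND"
  atom_label[prot] <- res_label[rkey[prot]]

  cg_beads <- which(prot & a$name == "CA" & atom_label == "CG")
  i_ca <- which(prot & a$name == "CA" & atom_label == "I")
  i_cb <- which(prot & a$name == "CB" & atom_label == "I")

  structure(list(atom_label = atom_label, res_label = res_label,
                 res_key = rkey, cg_beads = cg_beads,
                 interface_ca = i_ca, interface_cb = i_cb,
                 mm_cutoff = mm_cutoff, interface_cutoff = interface_cutoff),
            class = "mmcg_regions")
}

#' @export
print.mmcg_regions <- function(x, ...) {
  tab <- table(factor(x$res_label, levels = c("MM", "I", "CG")))
  cat("Region assignment:", tab["MM"], "MM,", tab["I"], "I,", tab["CG"],
      "CG residues;", sum(x$atom_label == "WATER", na.rm = TRUE),
      "water atoms;", sum(x$atom_label == "LIGAND", na.rm = TRUE),
      "ligand atoms\n")
  invisible(x)
}

# all-atomistic fallback for systems without protein or ligand (e.g. pure
# water droplets): every atom is labelled WATER/LIGAND/MM
#' @noRd
.trivial_regions <- function(structure) {
  a <- structure$atoms
  atom_label <- ifelse(a$is_water, "WATER", ifelse(a$is_ligand, "LIGAND", "MM"))
  prot <- !a$is_water & !a$is_ligand
  rkey <- paste(a$chain, a$resid)
  res_label <- setNames(rep("MM", length(unique(rkey[prot]))), unique(rkey[prot]))
  structure(list(atom_label = atom_label, res_label = res_label,
                 res_key = rkey, cg_beads = integer(0),
                 interface_ca = integer(0), interface_cb = integer(0),
                 mm_cutoff = NA_real_, interface_cutoff = NA_real_),
            class = "mmcg_regions")
}
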