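# Structure container and PDB I/O. Coordinates are stored in nm; PDB files
# (Angstrom) are converted at the I/O boundary.

#' Construct a structure object
#'
#' The central container of the package: one row per atom with residue and
#' chain identity, coordinates (nm), masses (amu), partial charges (e), and
#' water/ligand flags.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `mass`, `charge`,
#'   `is_water`, `is_ligand`.
#' @param validate validate invariants (finite coordinates, one C-alpha per
#'   protein residue, strictly increasing residue indices within a chain).
#' @return an object of class `mmcg_structure`.
#' @export
mmcg_structure <- function(atoms, validate = TRUE) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z", "mass", "charge", "is_water", "is_ligand")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  s <- structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
                 class = "mmcg_structure")
  if (validate) validate_structure(s)
  s
}

#' @rdname mmcg_structure
#' @param s an `mmcg_structure`.
#' @export
validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) stop("structure has no atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  if (any(a$mass <= 0)) stop("non-positive atomic mass")
  prot <- !a$is_water & !a$is_ligand
  if (any(prot)) {
    key <- paste(a$chain[prot], a$resid[prot])
    nca <- tapply(a$name[prot] == "CA", key, sum)
    if (any(nca != 1)) {
      bad <- names(nca)[nca != 1][1]
      stop("protein residue ", bad, " must have exactly one C-alpha atom")
    }
    for (ch in unique(a$chain[prot])) {
      r <- a$resid[prot & a$chain == ch]
      if (is.unsorted(unique(r), strictly = TRUE))
        stop("residue indices not strictly increasing in chain ", ch)
    }
  }
  invisible(s)
}

#' Atom coordinates as a matrix
#'
#' @param s an `mmcg_structure`.
#' @return numeric `n x 3` matrix in nm.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#'
#' @param s an `mmcg_structure`.
#' @param value `n x 3` matrix in nm.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]
  s$atoms$y <- value[, 2]
  s$atoms$z <- value[, 3]
  s
}

#' @export
print.mmcg_structure <- function(x, ...) {
  a <- x$atoms
  prot <- !a$is_water & !a$is_ligand
  nres <- length(unique(paste(a$chain[prot], a$resid[prot])))
  cat("MM/CG structure:", nrow(a), "atoms;", nres, "protein residues;",
      sum(a$is_water), "water atoms;", sum(a$is_ligand), "ligand atoms\n")
  invisible(x)
}

#' Number of atoms
#' @param s an `mmcg_structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (through bio3d), converts Angstrom to nm,
#' flags waters by residue name (HOH/SOL/WAT/...) and non-water HETATM
#' residues as ligand, and assigns element masses.
#'
#' @param path PDB file.
#' @param to_nm divide coordinates by 10 (default TRUE; the package works in
#'   nm internally).
#' @return an `mmcg_structure`.
#' @export
read_pdb <- function(path, to_nm = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  # validate coordinate fields before handing off to the parser, so a
  # malformed record is reported with its line number
  for (ln in which(rec)) {
    coordtxt <- substr(lines[ln], 31, 54)
    vals <- suppressWarnings(as.numeric(c(substr(coordtxt, 1, 8),
                                          substr(coordtxt, 9, 16),
                                          substr(coordtxt, 17, 24))))
    if (any(is.na(vals)))
      stop("malformed ATOM/HETATM record at line ", ln, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- ifelse(is.na(elem) | trimws(elem) == "",
                 guess_element(at$elety), toupper(trimws(elem)))
  water <- toupper(at$resid) %in% .water_resnames
  ligand <- at$type == "HETATM" & !water
  ch <- at$chain
  ch[is.na(ch)] <- "A"
  scale <- if (to_nm) 0.1 else 1.0
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ch,
    x = at$x * scale, y = at$y * scale, z = at$z * scale,
    mass = element_mass(elem),
    charge = 0.0,
    is_water = water,
    is_ligand = ligand,
    stringsAsFactors = FALSE
  )
  mmcg_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' Coordinates are converted from nm back to Angstrom. Water and ligand
#' atoms are written as HETATM so flags survive a read/write round trip.
#'
#' @param s an `mmcg_structure`.
#' @param path output file.
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "mmcg_structure")) stop("not an mmcg_structure")
  a <- s$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  lines <- .pdb_atom_lines(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' @noRd
.pdb_atom_lines <- function(a) {
  rec <- ifelse(a$is_water | a$is_ligand, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  sprintf("%6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm, substr(a$resname, 1, 3),
          substr(a$chain, 1, 1), a$resid %% 10000L,
          a$x * 10, a$y * 10, a$z * 10, 1.0, 0.0, a$element)
}
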