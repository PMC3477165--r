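# Atomistic (MM-region) parameter tables. The format is a flat, whitespace-
# delimited text file with record-type tags:
#
#   ATOM     <type> <mass> <sigma_nm> <eps_kJmol> <charge_e>
#   TYPEMAP  <resname|*> <atomname> <type>
#   BOND     <resname|*> <name1> <name2> <K_r kJ/mol/nm^2> <r0 nm>
#   ANGLE    <resname|*> <n1> <n2> <n3> <K_theta kJ/mol/rad^2> <theta0 deg>
#   DIHEDRAL <resname|*> <n1> <n2> <n3> <n4> <K_phi kJ/mol> <mult> <phase deg>
#   BACKBONE <name1> <name2> <K_r> <r0 nm>
#
# '*' matches any protein residue name. Lines starting with '#' are comments.
# The package ships a minimal self-consistent set for its synthetic systems
# (SPC water, pseudo C-alpha/C-beta residues, a 5-atom ligand chain); users
# supply their own table for real systems.

#' Read an MM parameter table
#'
#' @param path parameter file (see the package vignette for the format).
#' @return an object of class `mmcg_params` (lists of data frames).
#' @export
read_mm_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "\\s+")
  get <- function(tag, n, conv) {
    rows <- Filter(function(t) t[1] == tag, tok)
    if (length(rows) == 0) return(NULL)
    bad <- vapply(rows, length, 1L) != n + 1L
    if (any(bad)) stop("malformed ", tag, " record in ", path)
    m <- do.call(rbind, lapply(rows, function(t) t[-1]))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    for (k in seq_along(conv)) if (conv[k]) df[[k]] <- as.numeric(df[[k]])
    df
  }
  atoms <- get("ATOM", 5, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  if (is.null(atoms)) stop("parameter file has no ATOM records")
  names(atoms) <- c("type", "mass", "sigma", "eps", "charge")
  typemap <- get("TYPEMAP", 3, c(FALSE, FALSE, FALSE))
  if (is.null(typemap)) stop("parameter file has no TYPEMAP records")
  names(typemap) <- c("resname", "atomname", "type")
  bonds <- get("BOND", 5, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  if (!is.null(bonds)) names(bonds) <- c("resname", "n1", "n2", "k", "r0")
  angles <- get("ANGLE", 6, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  if (!is.null(angles)) names(angles) <- c("resname", "n1", "n2", "n3", "k", "theta0")
  dihedrals <- get("DIHEDRAL", 8, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  if (!is.null(dihedrals))
    names(dihedrals) <- c("resname", "n1", "n2", "n3", "n4", "k", "mult", "phase")
  backbone <- get("BACKBONE", 4, c(FALSE, FALSE, TRUE, TRUE))
  if (!is.null(backbone)) names(backbone) <- c("n1", "n2", "k", "r0")
  structure(list(atoms = atoms, typemap = typemap, bonds = bonds,
                 angles = angles, dihedrals = dihedrals, backbone = backbone),
            class = "mmcg_params")
}

#' Built-in toy parameter set
#'
#' The minimal self-consistent table shipped with the package: SPC water
#' (rigid 3-site), pseudo C-alpha/C-beta protein sites, and the 5-atom toy
#' ligand chain.
#'
#' @return an `mmcg_params`.
#' @export
default_mm_params <- function() {
  read_mm_params(system.file("extdata", "toy_forcefield.dat", package = "mmcg",
                             mustWork = TRUE))
}

#' @export
print.mmcg_params <- function(x, ...) {
  cat("MM parameter table:", nrow(x$atoms), "atom types,",
      nrow(x$typemap), "name mappings,",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bond records\n")
  invisible(x)
}
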