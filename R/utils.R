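# small shared helpers

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, `NA` = 22.990, K = 39.098,
  MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845
)

.water_resnames <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "SPC", "H2O")

#' @noRd
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(element[bad]), collapse = ", "),
            "; assigning mass 12.011")
    m[bad] <- 12.011
  }
  unname(m)
}

#' @noRd
guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  nm <- ifelse(nchar(nm) == 0, "C", nm)
  toupper(substr(nm, 1, 1))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vnorm <- function(m) sqrt(rowSums(m^2))

#' Select atom indices from a structure
#'
#' Resolves a selection to integer atom indices. `sel` may be an integer
#' vector (returned as-is), a logical vector over atoms, or one of the
#' keywords `"all"`, `"protein"`, `"calpha"`, `"backbone"` (alias for
#' C-alpha in the reduced representation used here), `"cbeta"`, `"water"`,
#' `"water_oxygen"`, `"ligand"`.
#'
#' @param structure an `mmcg_structure`.
#' @param sel selection (see Details).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, sel = "all") {
  a <- structure$atoms
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(a))
    return(which(sel))
  }
  stopifnot(is.character(sel), length(sel) == 1L)
  prot <- !a$is_water & !a$is_ligand
  idx <- switch(sel,
    all = seq_len(nrow(a)),
    protein = which(prot),
    calpha = which(prot & a$name == "CA"),
    backbone = which(prot & a$name == "CA"),
    cbeta = which(prot & a$name == "CB"),
    water = which(a$is_water),
    water_oxygen = which(a$is_water & a$element == "O"),
    ligand = which(a$is_ligand),
    stop("unknown selection keyword: ", sel)
  )
  idx
}

#' Resolve a named atom to its index
#'
#' Accepts `"chain:resid:name"` (e.g. `"A:12:CA"`) or `"resid:name"` when
#' the structure has a single chain.
#'
#' @param structure an `mmcg_structure`.
#' @param spec character atom specifier.
#' @return a single integer index.
#' @export
resolve_atom <- function(structure, spec) {
  a <- structure$atoms
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  rid <- parts[length(parts) - 1L]
  if (length(parts) < 2L || !grepl("^-?[0-9]+$", rid))
    stop("atom specifier must be 'chain:resid:name' or 'resid:name': ", spec)
  if (length(parts) == 2L) {
    hit <- which(a$resid == as.integer(parts[1]) & a$name == parts[2])
  } else if (length(parts) == 3L) {
    hit <- which(a$chain == parts[1] & a$resid == as.integer(parts[2]) &
                   a$name == parts[3])
  } else {
    stop("atom specifier must be 'chain:resid:name' or 'resid:name': ", spec)
  }
  if (length(hit) != 1L)
    stop("atom specifier '", spec, "' matched ", length(hit), " atoms")
  hit
}
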