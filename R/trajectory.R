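# Trajectory container plus plain-text trajectory formats (multi-model PDB
# and XYZ). Frame times are stamped in REMARK/comment lines.

#' Construct a trajectory
#'
#' @param structure reference `mmcg_structure` (atom identities).
#' @param frames `n x 3 x n_frames` array of coordinates (nm).
#' @param times frame times (ps), strictly increasing.
#' @param velocities optional `n x 3 x n_vframes` array (nm/ps).
#' @param vtimes times of the velocity frames (ps).
#' @param energies optional per-frame energy table.
#' @return an object of class `mmcg_trajectory`.
#' @export
mmcg_trajectory <- function(structure, frames, times, velocities = NULL,
                            vtimes = NULL, energies = NULL) {
  if (length(dim(frames)) != 3) stop("frames must be an n x 3 x n_frames array")
  if (dim(frames)[1] != n_atoms(structure))
    stop("frame atom count does not match the reference structure")
  if (dim(frames)[3] != length(times)) stop("times length != number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(structure = structure, frames = frames, times = times,
                 velocities = velocities, vtimes = vtimes, energies = energies),
            class = "mmcg_trajectory")
}

#' @export
print.mmcg_trajectory <- function(x, ...) {
  cat("MM/CG trajectory:", dim(x$frames)[3], "frames,", dim(x$frames)[1],
      "atoms, t =", min(x$times), "..", max(x$times), "ps\n")
  invisible(x)
}

#' Number of frames
#' @param traj an `mmcg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Coordinates of one frame
#' @param traj an `mmcg_trajectory`.
#' @param i frame index.
#' @return `n x 3` matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  traj$frames[, , i, drop = TRUE]
}

#' Write a trajectory to disk
#'
#' The format is chosen by extension: `.pdb` gives a multi-model PDB
#' (MODEL/ENDMDL, time in a REMARK line), `.xyz` a multi-frame XYZ with the
#' time in the comment line. Coordinates are written in Angstrom.
#'
#' @param traj an `mmcg_trajectory`.
#' @param path output file (`.pdb` or `.xyz`).
#' @param stride write every `stride`-th frame (>= 1).
#' @export
write_trajectory <- function(traj, path, stride = 1L) {
  if (n_frames(traj) == 0) stop("empty trajectory")
  if (stride < 1) stop("stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = as.integer(stride))
  ext <- tolower(tools::file_ext(path))
  a <- traj$structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "pdb") {
    for (k in seq_along(keep)) {
      fi <- keep[k]
      a[, c("x", "y", "z")] <- traj$frames[, , fi]
      writeLines(sprintf("REMARK   6 TIME= %.6f ps", traj$times[fi]), con)
      writeLines(sprintf("MODEL %8d", k), con)
      writeLines(.pdb_atom_lines(a), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (ext == "xyz") {
    for (fi in keep) {
      writeLines(as.character(nrow(a)), con)
      writeLines(sprintf("t= %.6f ps", traj$times[fi]), con)
      writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", a$element,
                         traj$frames[, 1, fi] * 10, traj$frames[, 2, fi] * 10,
                         traj$frames[, 3, fi] * 10), con)
    }
  } else {
    stop("unsupported trajectory extension: .", ext, " (use .pdb or .xyz)")
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path `.pdb` (multi-model) or `.xyz` file.
#' @param structure reference structure; required for `.xyz`, optional for
#'   `.pdb` (rebuilt from the first model otherwise).
#' @return an `mmcg_trajectory`.
#' @export
read_trajectory <- function(path, structure = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    lines <- readLines(path, warn = FALSE)
    times <- as.numeric(sub("^REMARK   6 TIME= ([0-9.eE+-]+) ps$", "\\1",
                            grep("^REMARK   6 TIME=", lines, value = TRUE)))
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz                      # n_frames x 3n, Angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    n <- ncol(xyz) / 3
    if (is.null(structure)) structure <- read_pdb(path)
    frames <- array(0, c(n, 3, nf))
    for (f in seq_len(nf))
      frames[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) * 0.1
    if (length(times) != nf) times <- seq_len(nf) - 1
    mmcg_trajectory(structure, frames, times)
  } else if (ext == "xyz") {
    if (is.null(structure)) stop("XYZ trajectories need a reference structure")
    lines <- readLines(path, warn = FALSE)
    n <- n_atoms(structure)
    block <- n + 2L
    nf <- length(lines) %/% block
    frames <- array(0, c(n, 3, nf))
    times <- numeric(nf)
    for (f in seq_len(nf)) {
      off <- (f - 1L) * block
      times[f] <- as.numeric(sub("^t= ([0-9.eE+-]+) ps$", "\\1", lines[off + 2L]))
      flds <- do.call(rbind, strsplit(trimws(lines[off + 2L + seq_len(n)]), "\\s+"))
      frames[, , f] <- apply(flds[, 2:4, drop = FALSE], 2, as.numeric) * 0.1
    }
    if (any(is.na(times))) times <- seq_len(nf) - 1
    mmcg_trajectory(structure, frames, times)
  } else {
    stop("unsupported trajectory extension: .", ext)
  }
}
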