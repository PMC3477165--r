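# Synthetic test systems with known geometry: ideal alpha-helical bundles
# (stand-ins for a transmembrane helix bundle), a small rigid ligand, and
# rigid 3-site water droplets confined by a wall set.

#' Generate an ideal helical bundle
#'
#' Builds `n_helices` ideal alpha-helical C-alpha traces (rise 0.15
#' nm/residue, helix radius 0.23 nm, 100 degrees/residue) with axes along z,
#' packed on a circle with ~1.1 nm spacing between neighbouring helix axes
#' (`max(0.9, 0.55 / sin(pi / n_helices))` nm ring radius) and alternating
#' in direction. Every residue carries a C-alpha and, except for
#' glycine-labelled residues, a pseudo C-beta 0.153 nm from the C-alpha
#' pointing away from the helix axis. A fraction of residues is labelled
#' GLY and TYR/TRP (seed-deterministic) so that glycine handling and
#' membrane-facing aromatics are exercised. Optionally a small rigid
#' 5-atom ligand chain is placed at the bundle center.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues per helix (>= 4).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param ligand also place a 5-atom ligand (resname LIG) at the center.
#' @return an `mmcg_structure`.
#' @export
generate_toy_bundle <- function(n_helices, residues_per_helix, seed = 1L,
                                ligand = FALSE) {
  if (n_helices < 1) stop("n_helices must be >= 1")
  if (residues_per_helix < 4) stop("residues_per_helix must be >= 4")
  set.seed(seed)
  rise <- 0.15; hrad <- 0.23; twist <- 100 * pi / 180
  # ring radius giving ~1.1 nm axis-to-axis spacing between neighbouring
  # helices (packed transmembrane-bundle geometry, so the Go model picks up
  # inter-helix native contacts), with a floor leaving room for the ligand
  ring <- if (n_helices == 1) 0 else max(0.9, 0.55 / sin(pi / n_helices))
  nres <- n_helices * residues_per_helix
  # seed-deterministic residue labels: ~10% GLY, ~10% TYR/TRP, rest ALA
  resnames <- rep("ALA", nres)
  lab <- sample(seq_len(nres))
  ngly <- max(1L, nres %/% 10L)
  naro <- max(1L, nres %/% 10L)
  resnames[lab[seq_len(ngly)]] <- "GLY"
  aro <- lab[ngly + seq_len(naro)]
  resnames[aro] <- sample(c("TYR", "TRP"), naro, replace = TRUE)
  phase <- stats::runif(n_helices, 0, 2 * pi)

  rows <- list()
  serial <- 0L
  resid <- 0L
  zlen <- (residues_per_helix - 1) * rise
  for (h in seq_len(n_helices)) {
    ang <- 2 * pi * (h - 1) / n_helices
    cx <- ring * cos(ang); cy <- ring * sin(ang)
    up <- (h %% 2L == 1L)
    # one chain per helix: the toy bundle has no connecting loops, so
    # consecutive-residue backbone bonds must not span helix junctions
    # ("L" and "W" are reserved for ligand and water chains)
    ch <- setdiff(LETTERS, c("L", "W"))[h]
    for (k in seq_len(residues_per_helix)) {
      resid <- resid + 1L
      t <- k - 1
      theta <- phase[h] + twist * t
      z <- if (up) -zlen / 2 + rise * t else zlen / 2 - rise * t
      ca <- c(cx + hrad * cos(theta), cy + hrad * sin(theta), z)
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "CA", element = "C",
        resname = resnames[resid], resid = resid, chain = ch,
        x = ca[1], y = ca[2], z = ca[3], mass = 12.011, charge = 0,
        is_water = FALSE, is_ligand = FALSE, stringsAsFactors = FALSE)
      if (resnames[resid] != "GLY") {
        u <- c(cos(theta), sin(theta), 0)       # radially out of the helix axis
        cb <- ca + 0.153 * u
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = "CB", element = "C",
          resname = resnames[resid], resid = resid, chain = ch,
          x = cb[1], y = cb[2], z = cb[3], mass = 12.011, charge = 0,
          is_water = FALSE, is_ligand = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  if (ligand) {
    lig <- .toy_ligand_coords()
    la <- data.frame(
      serial = max(atoms$serial) + seq_len(nrow(lig)),
      name = paste0("C", seq_len(nrow(lig))), element = "C",
      resname = "LIG", resid = 1L, chain = "L",
      x = lig[, 1], y = lig[, 2], z = lig[, 3],
      mass = 12.011, charge = 0, is_water = FALSE, is_ligand = TRUE,
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, la)
  }
  mmcg_structure(atoms)
}

# 5-atom tetrahedral zig-zag chain, bond 0.15 nm, angle 109.47 deg,
# centered at the origin
#' @noRd
.toy_ligand_coords <- function() {
  b <- 0.15
  th <- 109.47 * pi / 180
  p <- matrix(0, 5, 3)
  dirs <- list(c(1, 0, 0))
  for (k in 2:5) {
    prev <- dirs[[k - 1]]
    # alternate in the xz plane, keeping the tetrahedral bond angle
    ang <- pi - th
    s <- if (k %% 2 == 0) 1 else -1
    d <- c(prev[1] * cos(ang) - s * prev[3] * sin(ang), 0,
           s * prev[1] * sin(ang) + prev[3] * cos(ang))
    d <- d / sqrt(sum(d^2))
    dirs[[k]] <- d
  }
  for (k in 2:5) p[k, ] <- p[k - 1, ] + b * dirs[[k - 1]]
  sweep(p, 2, colMeans(p))
}

#' Generate a rigid water droplet inside a wall region
#'
#' Places `n_waters` rigid 3-site waters (O-H 0.1 nm, H-O-H 109.47 degrees,
#' SPC geometry) by rejection sampling strictly inside the positive
#' level-set region of `wallset` on the requested membrane side, keeping
#' every oxygen at least `min_spacing` from other oxygens and at least 0.25
#' nm from any atom of `exclude` (typically the protein). Deterministic for
#' a fixed seed.
#'
#' @param n_waters number of water molecules.
#' @param wallset a `mmcg_wallset` (see [build_walls()], [hemisphere_wallset()]).
#' @param side `"upper"` (extracellular) or `"lower"` droplet.
#' @param min_spacing minimum O-O distance (nm).
#' @param seed RNG seed.
#' @param exclude optional `mmcg_structure` whose atoms are avoided (0.25 nm).
#' @param margin keep oxygens at least this far inside the walls (nm).
#' @param max_attempts placement attempts per water before giving up.
#' @return an `mmcg_structure` of waters (resname SOL, atoms OW/HW1/HW2).
#' @export
generate_water_droplet <- function(n_waters, wallset, side = "upper",
                                   min_spacing = 0.26, seed = 1L,
                                   exclude = NULL, margin = 0.12,
                                   max_attempts = 2000L) {
  stopifnot(inherits(wallset, "mmcg_wallset"))
  set.seed(seed)
  if (side == "upper") {
    if (!wallset$active[3]) stop("wall set has no extracellular hemisphere")
    ctr <- wallset$chi3; rad <- wallset$r3
    zr <- c(wallset$z_hi, wallset$z_hi + rad)
  } else {
    if (!wallset$active[4]) stop("wall set has no cytoplasmic hemisphere")
    ctr <- wallset$chi4; rad <- wallset$r4
    zr <- c(wallset$z_lo - rad, wallset$z_lo)
  }
  if (diff(zr) <= 0 || rad <= margin)
    stop("wall region has no positive interior volume on side '", side, "'")
  excl_xyz <- if (!is.null(exclude)) coords(exclude) else NULL
  opos <- matrix(0, 0, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n_waters) {
    attempts <- attempts + 1L
    if (attempts > max_attempts * n_waters)
      stop("could not place all waters: placed ", placed, " of ", n_waters,
           " (region capacity exceeded at min_spacing = ", min_spacing, " nm)")
    p <- c(stats::runif(1, ctr[1] - rad, ctr[1] + rad),
           stats::runif(1, ctr[2] - rad, ctr[2] + rad),
           stats::runif(1, zr[1], zr[2]))
    wd <- wall_distance(matrix(p, 1, 3), wallset)
    if (wd$d[1] < margin) next
    if (!is.null(excl_xyz) &&
        min(vnorm(sweep(excl_xyz, 2, p))) < 0.25) next
    if (placed > 0L && min(vnorm(sweep(opos, 2, p))) < min_spacing) next
    opos <- rbind(opos, p)
    placed <- placed + 1L
  }
  # hydrogens: random orientation, SPC internal geometry
  doh <- 0.1
  half <- (109.47 / 2) * pi / 180
  rows <- vector("list", n_waters)
  for (w in seq_len(n_waters)) {
    # random orthonormal frame
    repeat {
      u <- stats::rnorm(3); nu <- sqrt(sum(u^2))
      if (nu > 1e-8) { u <- u / nu; break }
    }
    vtmp <- stats::rnorm(3)
    v <- vtmp - sum(vtmp * u) * u
    v <- v / sqrt(sum(v^2))
    h1 <- opos[w, ] + doh * (cos(half) * u + sin(half) * v)
    h2 <- opos[w, ] + doh * (cos(half) * u - sin(half) * v)
    rows[[w]] <- data.frame(
      serial = (w - 1L) * 3L + 1:3,
      name = c("OW", "HW1", "HW2"),
      element = c("O", "H", "H"),
      resname = "SOL", resid = w, chain = "W",
      x = c(opos[w, 1], h1[1], h2[1]),
      y = c(opos[w, 2], h1[2], h2[2]),
      z = c(opos[w, 3], h1[3], h2[3]),
      mass = c(15.999, 1.008, 1.008),
      charge = c(-0.82, 0.41, 0.41),
      is_water = TRUE, is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  mmcg_structure(do.call(rbind, rows))
}

#' Merge two structures into one
#'
#' Appends the atoms of `b` after those of `a` (serials renumbered).
#'
#' @param a,b `mmcg_structure` objects.
#' @return an `mmcg_structure`.
#' @export
merge_structures <- function(a, b) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  mmcg_structure(atoms)
}
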