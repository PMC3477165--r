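# Shared fixtures and numeric oracles for the test suites.

# Toy transmembrane bundle with the ligand displaced along z so that the
# MM / I / CG split puts helix termini in every region.
offset_ligand_bundle <- function(n_helices = 3, residues_per_helix = 24,
                                 seed = 1, dz = 1.2) {
  st <- generate_toy_bundle(n_helices, residues_per_helix, seed = seed,
                            ligand = TRUE)
  cx <- coords(st)
  lig <- st$atoms$is_ligand
  cx[lig, 3] <- cx[lig, 3] + dz
  coords(st) <- cx
  st
}

# Central finite-difference force check: returns the maximum relative error
# between -dE/dx and the analytic force over the probed atoms/components.
# `efun(x)` must return the scalar energy, `forces` the analytic n x 3 force
# matrix at `x`.
fd_max_rel_error <- function(efun, forces, x, atoms, h = 1e-6) {
  err <- 0
  for (i in atoms) {
    for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd <- -(efun(xp) - efun(xm)) / (2 * h)
      err <- max(err, abs(fd - forces[i, k]) / max(1, abs(forces[i, k])))
    }
  }
  err
}

# Brute-force gated wall level set: min over applicable walls, computed
# directly from the wall-set fields (independent of the C++ path).
oracle_wall_phi <- function(p, ws) {
  slab <- ws$active[5] && p[3] > ws$z_lo && p[3] < ws$z_hi
  vals <- c()
  if (ws$active[1] && !slab && !(ws$active[5] && p[3] < ws$z_hi))
    vals <- c(vals, p[3] - ws$z_hi)
  if (ws$active[2] && !slab && !(ws$active[5] && p[3] > ws$z_lo))
    vals <- c(vals, ws$z_lo - p[3])
  if (ws$active[3] && !slab && p[3] >= ws$z_hi)
    vals <- c(vals, ws$r3 - sqrt(sum((p - ws$chi3)^2)))
  if (ws$active[4] && !slab && p[3] <= ws$z_lo)
    vals <- c(vals, ws$r4 - sqrt(sum((p - ws$chi4)^2)))
  if (slab && nrow(ws$cj) > 0) {
    d <- sqrt(colSums((t(ws$cj) - p)^2))
    vals <- c(vals, ws$r_p - smooth_min(d, ws$beta))
  }
  if (length(vals) == 0) return(NA_real_)
  min(vals)
}
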