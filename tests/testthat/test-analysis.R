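# Analysis: superposition, RMSD/RMSF, VACF, RDF, distances.

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

test_that("Kabsch recovers a known rigid transform exactly", {
  set.seed(1)
  ref <- matrix(rnorm(60), 20, 3)
  r <- rot_z(0.7) %*% matrix(c(1, 0, 0, 0, cos(0.3), sin(0.3),
                               0, -sin(0.3), cos(0.3)), 3)
  x <- ref %*% t(r) + matrix(c(1, -2, 0.5), 20, 3, byrow = TRUE)
  k <- kabsch(x, ref)
  expect_lt(k$rmsd, 1e-12)
  expect_equal(k$xfit, ref, tolerance = 1e-10)
  expect_equal(det(k$rotation), 1)
  # mirror images are not matched by an improper rotation
  xm <- ref; xm[, 1] <- -xm[, 1]
  expect_equal(det(kabsch(xm, ref)$rotation), 1)
})

test_that("Kabsch RMSD agrees with bio3d fit.xyz", {
  set.seed(2)
  ref <- matrix(rnorm(45), 15, 3)
  x <- ref %*% t(rot_z(1.1)) + 0.05 * matrix(rnorm(45), 15, 3)
  k <- kabsch(x, ref)
  fx <- bio3d::fit.xyz(fixed = as.numeric(t(ref)), mobile = as.numeric(t(x)),
                       fixed.inds = 1:45, mobile.inds = 1:45)
  rb <- sqrt(mean(rowSums((matrix(fx, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(k$rmsd, rb, tolerance = 1e-6)
})

test_that("rmsd is zero under rigid motion and positive otherwise", {
  st <- generate_toy_bundle(2, 10, seed = 3)
  n <- n_atoms(st)
  base <- coords(st)
  nf <- 5
  fr <- array(0, c(n, 3, nf))
  for (k in seq_len(nf))
    fr[, , k] <- base %*% t(rot_z(0.2 * (k - 1))) + 0.1 * (k - 1)
  tr <- mmcg_trajectory(st, fr, times = 0:(nf - 1))
  r <- rmsd(tr)
  expect_lt(max(r$rmsd), 1e-10)
  rn <- rmsd(tr, fit = FALSE)
  expect_gt(rn$rmsd[2], 0.05)
})

test_that("rmsf matches the Gaussian oracle sqrt(3) sigma without fitting", {
  st <- generate_toy_bundle(2, 12, seed = 4)
  idx <- select_atoms(st, "calpha")
  n <- n_atoms(st)
  base <- coords(st)
  s <- 0.02
  nf <- 4000
  set.seed(5)
  fr <- array(rnorm(n * 3 * nf, 0, s), c(n, 3, nf)) + as.numeric(base)
  tr <- mmcg_trajectory(st, fr, times = seq_len(nf) - 1)
  r <- rmsf(tr, fit = FALSE)
  expect_equal(nrow(r), 24)
  expect_equal(mean(r$rmsf), sqrt(3) * s, tolerance = 0.02)
})

test_that("vacf reproduces the exponential decay of an AR(1) velocity", {
  tau <- 0.2; dt <- 0.01
  a <- exp(-dt / tau)
  na <- 200; nf <- 3000
  set.seed(6)
  v <- array(0, c(na, 3, nf))
  v[, , 1] <- rnorm(na * 3)
  for (k in 2:nf)
    v[, , k] <- a * v[, , k - 1] + sqrt(1 - a^2) * rnorm(na * 3)
  out <- vacf(v, times = (seq_len(nf) - 1) * dt, max_lag = 1.0)
  expect_equal(out$vacf[1], 1)
  want <- exp(-out$t / tau)
  expect_lt(max(abs(out$vacf - want)[out$t <= 0.5]), 0.05)
  dec <- attr(out, "decorrelation_time")
  expect_equal(dec, tau * log(1 / 0.05), tolerance = 0.15)
})

test_that("vacf input validation works", {
  st <- generate_toy_bundle(1, 6, seed = 7)
  fr <- array(0, c(n_atoms(st), 3, 3))
  tr <- mmcg_trajectory(st, fr + as.numeric(coords(st)), times = 0:2)
  expect_error(vacf(tr), "no stored velocities")
  v <- array(rnorm(18 * 4), c(18, 3, 4))
  expect_error(vacf(v), "times")
  expect_error(vacf(v, times = c(0, 1, 3, 7)), "uniformly spaced")
})

test_that("mc_region_volume reproduces the hemisphere volume", {
  hw <- hemisphere_wallset(radius = 2, z_plane = 0, side = "upper")
  v <- mc_region_volume(hw, n_samples = 4e5, seed = 2)
  expect_equal(as.numeric(v), 2 / 3 * pi * 8, tolerance = 0.02)
  expect_true(attr(v, "se") > 0)
})

test_that("rdf of ideal-gas points matches the bounded-region expectation", {
  # Uniform points in a hemisphere posing as water oxygens. The region is
  # finite and non-periodic, so g(r) dips below 1 as r grows (shells near
  # the boundary are partly outside the region); the exact ideal-gas curve
  # in this geometry is estimated by Monte Carlo over independent pairs.
  R <- 3
  sample_hemi <- function(n) {
    out <- matrix(0, 0, 3)
    while (nrow(out) < n) {
      p <- matrix(c(runif(2 * n, -R, R), runif(n, 0, R)), ncol = 3)
      p <- p[rowSums(p^2) < R^2, , drop = FALSE]
      out <- rbind(out, p)
    }
    out[seq_len(n), , drop = FALSE]
  }
  nw <- 400; nf <- 10
  set.seed(8)
  pts <- sample_hemi(nw)
  at <- data.frame(
    serial = seq_len(nw), name = "OW", element = "O", resname = "SOL",
    resid = seq_len(nw), chain = "W", x = pts[, 1], y = pts[, 2],
    z = pts[, 3], mass = 15.999, charge = 0, is_water = TRUE,
    is_ligand = FALSE)
  st <- mmcg_structure(at)
  fr <- array(0, c(nw, 3, nf))
  fr[, , 1] <- pts
  for (k in 2:nf) fr[, , k] <- sample_hemi(nw)
  tr <- mmcg_trajectory(st, fr, times = seq_len(nf) - 1)
  vol <- 2 / 3 * pi * R^3
  dr <- 0.05; r_max <- 1.2
  g <- rdf_oo(tr, volume = vol, r_max = r_max, dr = dr)
  # ideal-gas reference: P(pair distance in shell) * V / (4 pi r^2 dr)
  m <- 2e6
  dd <- sqrt(rowSums((sample_hemi(m) - sample_hemi(m))^2))
  p_shell <- tabulate(findInterval(dd[dd < r_max], seq(0, r_max, by = dr)),
                      nbins = length(g$r)) / m
  g_ref <- p_shell * vol / (4 * pi * g$r^2 * dr)
  sel <- g$r > 0.2   # skip the lowest-count innermost bins
  expect_lt(max(abs(g$g - g_ref)[sel]), 0.15)
  expect_equal(mean((g$g / g_ref)[sel]), 1, tolerance = 0.03)
  # and g is genuinely depressed at large r by the boundary
  expect_lt(g_ref[length(g_ref)], 0.95)
})

test_that("rdf picks up the first shell of a simple lattice", {
  # cubic lattice of "waters": nearest-neighbour peak at the lattice constant
  aL <- 0.31
  gr <- expand.grid(x = 0:5, y = 0:5, z = 0:5) * aL
  nw <- nrow(gr)
  at <- data.frame(
    serial = seq_len(nw), name = "OW", element = "O", resname = "SOL",
    resid = seq_len(nw), chain = "W", x = gr$x, y = gr$y, z = gr$z,
    mass = 15.999, charge = 0, is_water = TRUE, is_ligand = FALSE)
  st <- mmcg_structure(at)
  fr <- array(as.numeric(coords(st)), c(nw, 3, 1))
  tr <- mmcg_trajectory(st, fr, times = 0)
  g <- rdf_oo(tr, volume = (5 * aL)^3, r_max = 0.6, dr = 0.02)
  expect_equal(attr(g, "r_peak"), aL, tolerance = 0.02)
})

test_that("pair_distances recomputes plain Euclidean distances", {
  st <- generate_toy_bundle(1, 8, seed = 9)
  n <- n_atoms(st)
  nf <- 3
  set.seed(10)
  fr <- array(rnorm(n * 3 * nf), c(n, 3, nf))
  tr <- mmcg_trajectory(st, fr, times = 0:2)
  pd <- pair_distances(tr, rbind(c(1, 4), c(2, 7)))
  for (k in 1:nf) {
    expect_equal(pd$d1[k], sqrt(sum((fr[1, , k] - fr[4, , k])^2)))
    expect_equal(pd$d2[k], sqrt(sum((fr[2, , k] - fr[7, , k])^2)))
  }
  # selection-string interface
  pd2 <- pair_distances(tr, list("A:1:CA", "A:3:CA"))
  i1 <- resolve_atom(st, "A:1:CA"); i2 <- resolve_atom(st, "A:3:CA")
  expect_equal(pd2$d1[1], sqrt(sum((fr[i1, , 1] - fr[i2, , 1])^2)))
})
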