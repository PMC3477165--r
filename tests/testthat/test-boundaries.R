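# Level-set walls: geometry, potentials, forces, coupling, containment.

test_that("smooth_min matches its closed forms and bounds the hard min", {
  expect_equal(smooth_min(0.7, 50), 0.7)
  n <- 6; d <- rep(0.4, n); beta <- 50
  expect_equal(smooth_min(d, beta), 0.4 - log(n) / beta)
  set.seed(1)
  for (k in 1:20) {
    d <- runif(8, 0.1, 2)
    s <- smooth_min(d, 50)
    expect_lte(s, min(d))
    expect_gte(s, min(d) - log(length(d)) / 50)
  }
  # converges to the hard minimum as beta grows
  d <- c(0.3, 0.9, 1.4)
  expect_equal(smooth_min(d, 1e4), 0.3, tolerance = 1e-6)
  expect_error(smooth_min(numeric(0), 50))
  expect_error(smooth_min(0.5, -1))
})

test_that("wall set construction follows the protein geometry", {
  st <- generate_toy_bundle(3, 30, seed = 1)
  th <- 3.1; margin <- 2.0
  ws <- build_walls(st, membrane_thickness = th, water_margin = margin)
  a <- st$atoms
  cx <- coords(st)
  com <- colSums(cx * a$mass) / sum(a$mass)
  expect_equal(ws$z_hi - ws$z_lo, th)
  expect_equal((ws$z_hi + ws$z_lo) / 2, unname(com[3]))
  up <- cx[cx[, 3] > ws$z_hi, , drop = FALSE]
  expect_equal(ws$r3, max(sqrt(colSums((t(up) - ws$chi3)^2))) + margin)
  # every C-alpha is a membrane-wall source point
  expect_equal(ws$cj, unname(cx[a$name == "CA", , drop = FALSE]),
               ignore_attr = TRUE)
  # a short structure that never leaves the slab cannot define hemispheres
  flat <- generate_toy_bundle(3, 6, seed = 1)
  expect_error(build_walls(flat), "outside the membrane slab")
})

test_that("gated wall distance equals the brute-force level-set minimum", {
  st <- generate_toy_bundle(2, 30, seed = 2)
  ws <- build_walls(st)
  set.seed(3)
  pts <- cbind(runif(300, -4, 4), runif(300, -4, 4), runif(300, -5, 5))
  got <- wall_distance(pts, ws)$d
  want <- apply(pts, 1, oracle_wall_phi, ws = ws)
  ok <- !is.na(want)
  expect_gt(sum(ok), 250)
  expect_equal(got[ok], want[ok], tolerance = 1e-10)
})

test_that("phi5 reduces to r_p minus the distance field of the C-alphas", {
  st <- generate_toy_bundle(1, 30, seed = 1)
  ws <- build_walls(st)
  set.seed(4)
  pts <- cbind(runif(50, -1, 1), runif(50, -1, 1),
               runif(50, ws$z_lo + 0.05, ws$z_hi - 0.05))
  got <- wall_phi(pts, ws, which = 5)
  want <- vapply(seq_len(nrow(pts)), function(k) {
    d <- sqrt(colSums((t(ws$cj) - pts[k, ])^2))
    ws$r_p - smooth_min(d, ws$beta)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("attractive wall potential has its minimum exactly at r_p", {
  ws <- hemisphere_wallset(radius = 2, z_plane = 0)
  for (wall in 3:4) {
    d <- seq(0.001, ws$cut345, by = 1e-5)
    v <- wall_potential(d, wall, ws)
    expect_equal(d[which.min(v)], ws$r_p, tolerance = 1.1e-5)
    # depth at the minimum: eps + shift, with the unshifted zero at sigma
    x6 <- (ws$sigma_p / (ws$cut345 + ws$delta))^6
    e_shift <- 4 * ws$eps * (x6^2 - x6)
    expect_equal(wall_potential(ws$r_p, wall, ws), -ws$eps - e_shift)
    expect_equal(wall_potential(ws$sigma, wall, ws), -e_shift)
    # energy-shifted: continuous (zero) at the cutoff
    expect_equal(wall_potential(ws$cut345, wall, ws), 0)
    expect_lt(abs(wall_potential(ws$cut345 - 1e-7, wall, ws)), 1e-5)
  }
})

test_that("repulsive walls have compact support ending exactly at d_rep", {
  ws <- hemisphere_wallset(radius = 2, z_plane = 0)   # d_rep = 0.7 nm = 7 A
  for (wall in 1:2) {
    expect_identical(wall_potential(0.7, wall, ws), 0)
    expect_identical(wall_potential(0.9, wall, ws), 0)
    expect_gt(wall_potential(0.7 - 1e-9, wall, ws), 0)
    expect_identical(wall_force_profile(0.7, wall, ws), 0)
    expect_identical(wall_force_profile(1.2, wall, ws), 0)
    expect_gt(wall_force_profile(0.7 - 1e-6, wall, ws), 0)
  }
})

test_that("wall forces are capped at exactly f_max near and through zero", {
  ws <- hemisphere_wallset(radius = 2, z_plane = 0, f_max = 1000)
  for (wall in 1:4) {
    expect_identical(wall_force_profile(0, wall, ws), 1000)
    expect_identical(wall_force_profile(-0.3, wall, ws), 1000)
    expect_identical(wall_force_profile(1e-6, wall, ws), 1000)
    d <- seq(-0.1, 1.0, by = 1e-3)
    expect_true(all(abs(wall_force_profile(d, wall, ws)) <= 1000))
  }
})

test_that("the shifted, capped force profile is continuous", {
  ws <- hemisphere_wallset(radius = 2, z_plane = 0)
  # a genuine jump (e.g. an unshifted cutoff) would appear as a diff of the
  # size of the force shift (~4.2 for the attractive walls); smooth slopes
  # on this grid stay well below 0.5
  for (wall in c(1, 3)) {
    d <- seq(-0.01, 0.75, by = 1e-6)
    f <- wall_force_profile(d, wall, ws)
    expect_lt(max(abs(diff(f))), 0.5)
    # energy-shifted potential vanishes continuously at its cutoff
    dcut <- if (wall == 1) ws$d_rep else ws$cut345
    expect_lt(abs(wall_potential(dcut - 1e-7, wall, ws)), 1e-4)
  }
})

test_that("wall forces are the exact gradient of the reported wall energy", {
  st <- generate_toy_bundle(3, 24, seed = 1, ligand = TRUE)
  ws <- build_walls(st)
  cx <- coords(st)
  set.seed(5)
  cx <- cx + matrix(rnorm(length(cx), 0, 0.02), nrow(cx))
  wf <- wall_forces(cx, ws)
  err <- fd_max_rel_error(function(x) wall_forces(x, ws)$energy, wf$forces,
                          cx, ws$coupled$atom[seq(1, nrow(ws$coupled), 7)])
  expect_lt(err, 1e-5)

  hw <- hemisphere_wallset(radius = 2, z_plane = 0)
  wat <- generate_water_droplet(20, hw, seed = 2)
  cw <- coords(wat)
  all_idx <- seq_len(nrow(cw))
  wf2 <- wall_forces(cw, hw, coupled = all_idx)
  err2 <- fd_max_rel_error(function(x) wall_forces(x, hw, coupled = all_idx)$energy,
                           wf2$forces, cw, seq(1, nrow(cw), by = 7))
  expect_lt(err2, 1e-5)
})

test_that("coupled-atom list separates water and membrane-anchored modes", {
  st <- generate_toy_bundle(3, 24, seed = 1, ligand = TRUE)
  hw <- build_walls(st)
  wat_ws <- hemisphere_wallset(radius = 1.5, z_plane = hw$z_hi, side = "upper")
  wat <- generate_water_droplet(5, wat_ws, seed = 3)
  m <- merge_structures(st, wat)
  ws <- build_walls(m)
  cp <- ws$coupled
  a <- m$atoms
  # all water atoms coupled with mode 0
  expect_setequal(cp$atom[cp$mode == 0], which(a$is_water))
  # all protein C-alphas coupled with mode 1
  ca <- which(!a$is_water & !a$is_ligand & a$name == "CA")
  expect_true(all(ca %in% cp$atom[cp$mode == 1]))
  # ligand atoms are never wall-coupled
  expect_false(any(which(a$is_ligand) %in% cp$atom))
  # toy pseudo C-beta sits inside the phi5 repulsive core and is excluded
  cb <- which(!a$is_water & !a$is_ligand & a$name == "CB")
  expect_false(any(cb %in% cp$atom))
  # mode-1 atoms start essentially at the potential minimum d = r_p
  p5 <- wall_forces(coords(m), ws)
  f_ca <- sqrt(rowSums(p5$forces[ca, , drop = FALSE]^2))
  expect_lt(max(f_ca), 1e-6)
})

test_that("water stays inside the positive level-set region during dynamics", {
  hw <- hemisphere_wallset(radius = 2, z_plane = 0, side = "upper")
  wat <- generate_water_droplet(60, hw, seed = 7)
  cfg <- mmcg_config(n_steps = 1500, out_stride = 25, seed = 2)
  run <- run_simulation(wat, config = cfg, wallset = hw)
  worst <- Inf
  for (k in seq_len(n_frames(run$trajectory))) {
    d <- wall_distance(frame_coords(run$trajectory, k), hw)$d
    worst <- min(worst, min(d))
  }
  expect_gt(worst, 0)
})

test_that("sigma above the geometric bound is rejected", {
  expect_error(hemisphere_wallset(radius = 2, z_plane = 0, sigma = 0.19),
               "sigma must be")
})
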