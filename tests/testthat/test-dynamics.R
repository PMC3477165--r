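# Stochastic dynamics engine: integrator limits, thermostat, constraints,
# neighbour list, reproducibility, checkpoints, configuration I/O.

test_that("the configuration container validates and round-trips", {
  cfg <- mmcg_config(n_steps = 123L, temperature = 310, seed = 9)
  expect_s3_class(cfg, "mmcg_config")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$n_steps, 123L)
  expect_equal(cfg2$temperature, 310)
  expect_equal(cfg2$timestep, cfg$timestep)
  writeLines(c("timestep = 0.002", "no_such_option = 1"), path)
  expect_error(read_run_config(path), "no_such_option")
})

test_that("initial velocities are Maxwell-Boltzmann with zero drift", {
  hw <- hemisphere_wallset(radius = 3, z_plane = 0)
  wat <- generate_water_droplet(150, hw, seed = 1)
  v <- init_velocities(wat, temperature = 300, seed = 42)
  m <- wat$atoms$mass
  # no centre-of-mass drift
  expect_lt(max(abs(colSums(v * m) / sum(m))), 1e-12)
  # kinetic temperature near the setpoint (450 atoms, ~3% statistical noise)
  kin <- 0.5 * sum(m * rowSums(v^2))
  temp <- 2 * kin / (3 * nrow(v) * kB())
  expect_lt(abs(temp - 300) / 300, 0.1)
  expect_equal(init_velocities(wat, temperature = 300, seed = 42), v)
  expect_true(all(init_velocities(wat, temperature = 0) == 0))
})

test_that("SHAKE restores constraints and conserves them along a run", {
  hw <- hemisphere_wallset(radius = 1.5, z_plane = 0)
  wat <- generate_water_droplet(10, hw, seed = 2)
  reg <- NULL
  top <- build_hybrid_topology(wat, reg)
  cons <- top$constraints
  expect_equal(nrow(cons), 30)   # 3 per rigid water
  x0 <- coords(wat)
  set.seed(3)
  xd <- x0 + matrix(rnorm(length(x0), 0, 0.005), nrow(x0))
  xs <- shake(x0, xd, cons, wat$atoms$mass, tol = 1e-8)
  dd <- sqrt(rowSums((xs[cons$i, ] - xs[cons$j, ])^2))
  expect_lt(max(abs(dd - cons$d) / cons$d), 1e-8)

  # drift along a thermostatted run stays below 1e-5
  run <- run_simulation(wat, config = mmcg_config(n_steps = 1000,
                                                  out_stride = 100, seed = 4),
                        wallset = hw)
  for (k in seq_len(n_frames(run$trajectory))) {
    xk <- frame_coords(run$trajectory, k)
    dk <- sqrt(rowSums((xk[cons$i, ] - xk[cons$j, ])^2))
    expect_lt(max(abs(dk - cons$d) / cons$d), 1e-5)
  }
})

test_that("Langevin friction decays free velocities as exp(-t/tau)", {
  # one free atom, no forces: OBABO gives v_{n+1} = exp(-dt/tau) v_n exactly
  m <- mmcg_structure(data.frame(
    serial = 1L, name = "CA", element = "C", resname = "GLY", resid = 1L,
    chain = "A", x = 0, y = 0, z = 0, mass = 12.011, charge = 0,
    is_water = FALSE, is_ligand = FALSE))
  top <- build_hybrid_topology(m, NULL)
  cfg <- mmcg_config(timestep = 0.002, tau = 0.4, temperature = 0, seed = 1)
  st <- mmcg_state(positions = coords(m), velocities = matrix(c(1, 0, 0), 1))
  for (k in 1:50) st <- sd_step(st, top, NULL, cfg)
  expect_equal(st$velocities[1, 1], exp(-50 * 0.002 / 0.4), tolerance = 1e-10)
  # and the position advances ballistically between decays
  expect_gt(st$positions[1, 1], 0)
})

test_that("NVE total energy is conserved without friction (0.5 fs, 10 ps)", {
  st <- offset_ligand_bundle()
  cfg <- mmcg_config(timestep = 5e-4, n_steps = 20000, out_stride = 500,
                     seed = 4, tau = 0, mm_cutoff = 0.8)
  run <- run_simulation(st, config = cfg)
  e <- run$trajectory$energies$e_total
  expect_lt(abs(e[length(e)] - e[1]) / abs(e[1]), 1e-4)
  # and the per-term split sums to the reported potential
  en <- run$trajectory$energies
  expect_equal(en$e_mm + en$e_i + en$e_mmi + en$e_cg + en$e_cgi + en$e_wall,
               en$e_pot, tolerance = 1e-10)
})

test_that("the thermostat holds the setpoint temperature", {
  hw <- hemisphere_wallset(radius = 2, z_plane = 0)
  wat <- generate_water_droplet(100, hw, seed = 7)
  cfg <- mmcg_config(n_steps = 6000, out_stride = 25, seed = 3,
                     temperature = 300, tau = 0.4)
  run <- run_simulation(wat, config = cfg, wallset = hw)
  Tm <- run$trajectory$energies$temperature
  n <- length(Tm)
  expect_lt(abs(mean(Tm[(n %/% 3):n]) - 300) / 300, 0.05)
})

test_that("neighbour-list dynamics reproduces the brute-force energy", {
  st <- offset_ligand_bundle()
  cfg <- mmcg_config(n_steps = 50, out_stride = 10, seed = 6, mm_cutoff = 0.8,
                     minimize = FALSE)
  run <- run_simulation(st, config = cfg)
  reg <- run$regions
  top <- run$topology
  en <- run$trajectory$energies
  for (k in c(1, n_frames(run$trajectory))) {
    xk <- frame_coords(run$trajectory, k)
    ref <- total_energy(xk, top, run$wallset)   # fresh exact pair list
    expect_equal(en$e_pot[k], ref$report$total, tolerance = 1e-9)
  }
})

test_that("identical seeds give bitwise identical trajectories", {
  st <- offset_ligand_bundle()
  cfg <- mmcg_config(n_steps = 300, out_stride = 50, seed = 11, mm_cutoff = 0.8)
  r1 <- run_simulation(st, config = cfg)
  r2 <- run_simulation(st, config = cfg)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$trajectory$energies, r2$trajectory$energies)
  cfg2 <- mmcg_config(n_steps = 300, out_stride = 50, seed = 12, mm_cutoff = 0.8)
  r3 <- run_simulation(st, config = cfg2)
  expect_false(identical(r1$trajectory$frames, r3$trajectory$frames))
})

test_that("steepest-descent minimisation reduces energy and forces", {
  st <- offset_ligand_bundle()
  reg <- assign_regions(st, mm_cutoff = 0.8)
  top <- build_hybrid_topology(st, reg)
  cx <- coords(st)
  set.seed(13)
  cx <- cx + matrix(rnorm(length(cx), 0, 0.01), nrow(cx))
  e0 <- total_energy(cx, top)$report$total
  mn <- minimize_sd(cx, top, tol = 50)
  expect_lt(mn$energy, e0)
  expect_lt(mn$max_force, 50)
})

test_that("checkpoints round-trip the full state", {
  st <- offset_ligand_bundle()
  cfg <- mmcg_config(n_steps = 100, seed = 14, mm_cutoff = 0.8)
  run <- run_simulation(st, config = cfg)
  path <- withr::local_tempfile(fileext = ".chk")
  save_checkpoint(run$state, path)
  st2 <- load_checkpoint(path)
  expect_equal(st2$positions, unname(run$state$positions), tolerance = 1e-12)
  expect_equal(st2$velocities, unname(run$state$velocities), tolerance = 1e-12)
  expect_equal(st2$time, run$state$time)
  expect_equal(st2$step, run$state$step)
})

test_that("trajectory bookkeeping is consistent", {
  st <- offset_ligand_bundle()
  cfg <- mmcg_config(n_steps = 200, out_stride = 40, vel_stride = 40,
                     seed = 15, mm_cutoff = 0.8)
  run <- run_simulation(st, config = cfg)
  tr <- run$trajectory
  expect_equal(n_frames(tr), 6)              # initial frame + 5 strided
  expect_equal(diff(tr$times), rep(40 * cfg$timestep, 5))
  expect_equal(dim(tr$velocities)[3], 6)
  # reported temperature matches the kinetic energy definition
  en <- tr$energies
  expect_equal(en$e_total, en$e_pot + en$e_kin, tolerance = 1e-10)
})
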