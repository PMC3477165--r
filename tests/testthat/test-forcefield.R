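# Hybrid energy terms: closed-form oracles, finite-difference force checks,
# Newton's third law, and a brute-force nonbonded reference.

test_that("Go harmonic bond matches its closed form", {
  x <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  pr <- data.frame(i = 1, j = 2, k_b = 1000, b0 = 0.38)
  e <- go_bonded_energy(x, pr)
  expect_equal(e$energy, 0.5 * 1000 * (0.5 - 0.38)^2)
  expect_equal(e$forces[2, 1], -1000 * (0.5 - 0.38))
  expect_equal(e$forces[1, ], -e$forces[2, ])
  # zero at the native distance
  x0 <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  expect_equal(go_bonded_energy(x0, pr)$energy, 0)
})

test_that("Morse contact has depth V0 at b0 and dissociates to zero", {
  b0 <- 0.5; B <- 5 + 6 / b0; v0 <- 5.3
  ct <- data.frame(i = 1, j = 2, b0 = b0, B = B, v0 = v0)
  at_r <- function(r)
    go_morse_energy(rbind(c(0, 0, 0), c(r, 0, 0)), ct)$energy
  expect_equal(at_r(b0), -v0)
  expect_lt(abs(at_r(50)), 1e-8)
  # closed form at an arbitrary separation
  r <- 0.7
  expect_equal(at_r(r), v0 * ((1 - exp(-B * (r - b0)))^2 - 1))
  # force vanishes at the minimum
  f <- go_morse_energy(rbind(c(0, 0, 0), c(b0, 0, 0)), ct)$forces
  expect_lt(max(abs(f)), 1e-10)
})

test_that("well depth over a dense grid equals V0 for any b0", {
  for (b0 in c(0.4, 0.5, 0.8, 1.1)) {
    B <- 5 + 6 / b0
    ct <- data.frame(i = 1, j = 2, b0 = b0, B = B, v0 = 5.3)
    r <- seq(0.05, 5, by = 1e-3)
    e <- vapply(r, function(ri)
      go_morse_energy(rbind(c(0, 0, 0), c(ri, 0, 0)), ct)$energy, numeric(1))
    expect_equal(e[length(e)] - min(e), 5.3, tolerance = 1e-6)
  }
})

test_that("analytic forces of every term match finite differences", {
  st <- offset_ligand_bundle()
  reg <- assign_regions(st, mm_cutoff = 0.8)
  top <- build_hybrid_topology(st, reg)
  ws <- build_walls(st)
  cx <- coords(st)
  set.seed(11)
  cx <- cx + matrix(rnorm(length(cx), 0, 0.01), nrow(cx))
  probe <- seq(1, nrow(cx), by = 9)

  te <- total_energy(cx, top, ws)
  err <- fd_max_rel_error(function(x) total_energy(x, top, ws)$report$total,
                          te$forces, cx, probe)
  expect_lt(err, 1e-5)

  # the separate term evaluators agree with their own gradients too
  me <- mm_energy(cx, top)
  errm <- fd_max_rel_error(function(x) mm_energy(x, top)$energy,
                           me$forces, cx, probe)
  expect_lt(errm, 1e-5)

  gm <- go_morse_energy(cx, top$go_contacts)
  beads <- unique(c(top$go_contacts$i, top$go_contacts$j))
  errg <- fd_max_rel_error(function(x) go_morse_energy(x, top$go_contacts)$energy,
                           gm$forces, cx, beads[seq(1, length(beads), by = 5)])
  expect_lt(errg, 1e-5)
})

test_that("forces sum to zero (Newton's third law) for internal terms", {
  st <- offset_ligand_bundle()
  reg <- assign_regions(st, mm_cutoff = 0.8)
  top <- build_hybrid_topology(st, reg)
  cx <- coords(st)
  set.seed(12)
  cx <- cx + matrix(rnorm(length(cx), 0, 0.01), nrow(cx))
  expect_lt(max(abs(colSums(mm_energy(cx, top)$forces))), 1e-8)
  expect_lt(max(abs(colSums(go_morse_energy(cx, top$go_contacts)$forces))), 1e-8)
  expect_lt(max(abs(colSums(go_bonded_energy(cx, top$go_bonds)$forces))), 1e-8)
  expect_lt(max(abs(colSums(coupling_energy(cx, top)$forces))), 1e-8)
})

test_that("nonbonded energy matches a plain-R brute force with energy shift", {
  # small atomistic-only system: the displaced ligand plus nearby waters
  hw <- hemisphere_wallset(radius = 1.2, z_plane = 0, side = "upper")
  wat <- generate_water_droplet(6, hw, seed = 5)
  st <- generate_toy_bundle(1, 5, seed = 1, ligand = TRUE)
  lig <- st$atoms[st$atoms$is_ligand, ]
  lig$z <- lig$z + 0.6
  m <- merge_structures(mmcg_structure(lig, validate = FALSE), wat)
  top <- build_hybrid_topology(m, NULL)
  cutoff <- 1.6
  e <- mm_energy(coords(m), top, cutoff = cutoff)

  # brute force in R from the same parameter assignments
  par <- default_mm_params()
  a <- m$atoms
  key <- ifelse(a$is_water, "SOL", ifelse(a$is_ligand, "LIG", "*"))
  ty <- vapply(seq_len(nrow(a)), function(i) {
    tm <- par$typemap
    hit <- tm$type[(tm$resname == key[i] | tm$resname == "*") &
                     tm$atomname == a$name[i]]
    hit[1]
  }, character(1))
  ai <- match(ty, par$atoms$type)
  sig <- par$atoms$sigma[ai]; eps <- par$atoms$eps[ai]; q <- par$atoms$charge[ai]
  cx <- coords(m)
  fpe <- 138.935458
  # exclusions: all intra-molecular pairs of this small system (bonds + angles
  # + water constraint trio); molecules here are <= 5 atoms, exclude by residue
  mol <- paste(a$chain, a$resid)
  eref <- 0
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (mol[i] == mol[j] &&
        !(a$is_ligand[i] && abs(i - j) > 2)) next  # ligand 1-4+ pairs included
    r <- sqrt(sum((cx[i, ] - cx[j, ])^2))
    if (r >= cutoff) next
    s <- 0.5 * (sig[i] + sig[j]); ee <- sqrt(eps[i] * eps[j])
    lj <- function(rr) {
      x6 <- (s / rr)^6
      4 * ee * (x6^2 - x6)
    }
    cl <- function(rr) fpe * q[i] * q[j] / rr
    eref <- eref + (lj(r) - lj(cutoff)) + (cl(r) - cl(cutoff))
  }
  expect_equal(e$energy, eref, tolerance = 1e-9)
})

test_that("nonbonded energy shift makes the pair energy continuous at cutoff", {
  # two lone C-alpha "residues" in different chains: no bonds, no exclusions
  m <- mmcg_structure(data.frame(
    serial = 1:2, name = "CA", element = "C", resname = "ALA", resid = 1L,
    chain = c("A", "B"), x = c(0, 1), y = 0, z = 0, mass = 12.011,
    charge = 0, is_water = FALSE, is_ligand = FALSE))
  top <- build_hybrid_topology(m, NULL)
  cutoff <- 1.6
  at_r <- function(r)
    mm_energy(rbind(c(0, 0, 0), c(r, 0, 0)), top, cutoff = cutoff)$energy
  expect_equal(at_r(cutoff + 1e-9), 0)
  expect_lt(abs(at_r(cutoff - 1e-6)), 1e-8)
  expect_false(at_r(0.4) == 0)
})

test_that("coupling terms use Go functional forms on CG/I pairs only", {
  st <- offset_ligand_bundle()
  reg <- assign_regions(st, mm_cutoff = 0.8)
  top <- build_hybrid_topology(st, reg)
  lab <- reg$atom_label
  expect_true(all(lab[top$cpl_bonds$i] == "CG" | lab[top$cpl_bonds$j] == "CG"))
  expect_true(all(lab[top$cpl_bonds$i] == "I" | lab[top$cpl_bonds$j] == "I"))
  expect_true(all(lab[top$cpl_contacts$i] == "CG" | lab[top$cpl_contacts$j] == "CG"))
  # at the native structure every Go and coupling term is at its minimum
  cx <- coords(st)
  expect_equal(go_bonded_energy(cx, top$go_bonds)$energy, 0)
  expect_lt(max(abs(coupling_energy(cx, top)$forces +
                    go_bonded_energy(cx, top$go_bonds)$forces +
                    go_morse_energy(cx, top$go_contacts)$forces)), 1e-9)
})

test_that("B_ij follows the membrane rule B_const + 6/b0", {
  st <- offset_ligand_bundle()
  reg <- assign_regions(st, mm_cutoff = 0.8)
  top <- build_hybrid_topology(st, reg, go_params = list(K_b = 1000, V_0 = 5.3,
                                                         B_const = 5))
  expect_equal(top$go_contacts$B, 5 + 6 / top$go_contacts$b0)
  tops <- build_hybrid_topology(st, reg, go_params = list(B_const = 0))
  expect_equal(tops$go_contacts$B, 6 / tops$go_contacts$b0)
})

test_that("parameter files are parsed and validated", {
  par <- default_mm_params()
  expect_s3_class(par, "mmcg_params")
  expect_true(all(c("type", "sigma", "eps", "charge") %in% names(par$atoms)))
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines("ATOM CAP 12.011 0.35", bad)   # too few fields
  expect_error(read_mm_params(bad), "malformed ATOM")
  writeLines("TYPEMAP * CA CAP", bad)
  expect_error(read_mm_params(bad), "no ATOM records")
})
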